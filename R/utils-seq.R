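#' Reverse complement of DNA strings
#'
#' Vectorized over `x`. Ambiguous bases (`N`) are preserved.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# internal: one base-frequency pass, shared by compute_gc() and skew
.base_counts <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  tabulate(factor(ch, levels = c("A", "C", "G", "T")), nbins = 4L)
}

#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguous bases are excluded from
#' both numerator and denominator. A sequence with no unambiguous base has
#' undefined GC and returns `NA_real_`.
#'
#' @param sequence A single DNA string.
#' @return GC fraction in `[0, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' compute_gc("ACGTN")  # 0.5: the N is dropped
compute_gc <- function(sequence) {
  n <- .base_counts(sequence)
  tot <- sum(n)
  if (tot == 0L) return(NA_real_)
  (n[2] + n[3]) / tot
}

# The 136 canonical tetranucleotides: each 4-mer pooled with its reverse
# complement, the canonical representative being the lexicographic minimum.
# 256 4-mers collapse to 136 classes (16 are their own reverse complement).
.tnf_tables <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    bases <- c("A", "C", "G", "T")
    all4 <- do.call(paste0, expand.grid(bases, bases, bases, bases,
                                        stringsAsFactors = FALSE)[, 4:1])
    all4 <- sort(all4)
    rc <- revcomp(all4)
    canon <- pmin(all4, rc)
    keys <- sort(unique(canon))
    tbl <<- list(all4 = all4, canon = canon, keys = keys,
                 index = match(canon, keys))
    tbl
  }
})

#' Canonical tetranucleotide names
#'
#' The 136 canonical 4-mers (lexicographic minimum of each
#' forward/reverse-complement pair), in lexicographic order. This is the
#' column ordering of every TNF vector the package produces.
#'
#' @return Character vector of length 136.
#' @export
tnf_keys <- function() .tnf_tables()$keys

#' Tetranucleotide frequency (TNF) vector
#'
#' Counts every overlapping 4-mer of the sequence, pooling each 4-mer with
#' its reverse complement into 136 canonical classes, and normalizes to a
#' frequency vector. 4-mers containing an ambiguous base are skipped.
#' Sequences shorter than 4 bp (or with no unambiguous 4-mer) yield an
#' all-zero vector carrying attribute `valid = FALSE`.
#'
#' @param sequence A single DNA string over A/C/G/T/N.
#' @return Named numeric vector of length 136 summing to 1 when valid.
#' @export
#' @examples
#' compute_tnf("ACGT")["ACGT"]  # the full mass: ACGT is its own revcomp
compute_tnf <- function(sequence) {
  t4 <- .tnf_tables()
  out <- stats::setNames(numeric(length(t4$keys)), t4$keys)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 4L) {
    attr(out, "valid") <- FALSE
    return(out)
  }
  kmers <- substring(s, 1:(n - 3L), 4:n)
  idx <- t4$index[match(kmers, t4$all4)]   # NA for 4-mers containing N
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    attr(out, "valid") <- FALSE
    return(out)
  }
  cnt <- tabulate(idx, nbins = length(t4$keys))
  out[] <- cnt / sum(cnt)
  attr(out, "valid") <- TRUE
  out
}

#' Per-scaffold sequence features
#'
#' Computes length, GC content and the 136-entry canonical TNF vector for
#' every scaffold in a table, the feature set used by the binning stage
#' alongside coverage.
#'
#' @param scaffolds Data frame with columns `scaffold` and `sequence`.
#' @param depth Optional data frame of windowed depth (`scaffold`,
#'   `window_start`, `window_end`, `depth`); when supplied, a
#'   length-weighted `mean_depth` column is added.
#' @return A tibble with columns `scaffold`, `length`, `gc`, `tnf` (a
#'   list-column of 136-entry vectors) and optionally `mean_depth`.
#' @export
scaffold_features <- function(scaffolds, depth = NULL) {
  stopifnot(all(c("scaffold", "sequence") %in% names(scaffolds)))
  feats <- tibble::tibble(
    scaffold = scaffolds$scaffold,
    length = nchar(scaffolds$sequence),
    gc = vapply(scaffolds$sequence, compute_gc, numeric(1), USE.NAMES = FALSE),
    tnf = lapply(scaffolds$sequence, compute_tnf)
  )
  if (!is.null(depth)) {
    d <- dplyr::group_by(depth, .data$scaffold)
    d <- dplyr::summarise(
      d,
      mean_depth = stats::weighted.mean(.data$depth,
                                        .data$window_end - .data$window_start),
      .groups = "drop"
    )
    feats <- dplyr::left_join(feats, d, by = "scaffold")
  }
  feats
}
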