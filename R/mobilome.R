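#' Default chromosomal-MGE keyword lists
#'
#' A reconstruction of the published keyword scheme for classifying gene
#' product descriptions into mobile-genetic-element classes. The lists
#' are matched case-insensitively as substrings, in the fixed priority
#' transposon > plasmid > phage > other; edit or replace them via the
#' `keywords` argument of [classify_cmge()].
#'
#' @return Named list of character vectors.
#' @export
mge_keywords <- function() {
  list(
    transposon = c("transposase", "transposon", "insertion sequence",
                   "IS element", "transposition"),
    plasmid = c("plasmid", "conjugal transfer", "conjugative transfer",
                "conjugation", "mobilization protein", "mobilisation",
                "relaxase", "type IV secretion", "tra gene", "trb"),
    phage = c("phage", "prophage", "capsid", "terminase", "tail protein",
              "tail fiber", "tail fibre", "portal protein", "holin",
              "baseplate", "virion"),
    other = c("integrase", "recombinase", "mobile element", "resolvase",
              "excisionase")
  )
}

#' Classify a gene product as a chromosomal MGE
#'
#' Case-insensitive substring search of the product description against
#' the class keyword lists, in fixed priority order (transposon, then
#' plasmid, phage, other). No match yields `none`.
#'
#' @param product Character vector of product descriptions.
#' @param keywords Keyword lists (default [mge_keywords()]).
#' @return Character vector of classes, with attribute-free `none` for
#'   unmatched products.
#' @export
#' @examples
#' classify_cmge("Tn3 family transposase")
classify_cmge <- function(product, keywords = mge_keywords()) {
  out <- rep("none", length(product))
  low <- tolower(product)
  for (cls in c("transposon", "plasmid", "phage", "other")) {
    hit <- Reduce(`|`, lapply(tolower(keywords[[cls]]),
                              function(kw) grepl(kw, low, fixed = TRUE)))
    out[out == "none" & hit] <- cls
  }
  out
}

#' MGE density per Mbp
#'
#' Normalizes per-class MGE counts by genome size so that incomplete
#' genomes do not look MGE-poor merely because they are short.
#'
#' @param counts Named vector (or tibble column) of per-class counts.
#' @param genome_size Genome size in bp (> 0).
#' @return Counts per Mbp, same shape as `counts`.
#' @export
mge_density <- function(counts, genome_size) {
  if (any(genome_size <= 0)) stop("genome size must be > 0")
  counts * 1e6 / genome_size
}

#' Compare MGE densities between abundance tiers
#'
#' Two-sample Wilcoxon rank-sum tests of per-bin MGE densities between
#' every pair of abundance tiers, per MGE class (exact p-values for small
#' samples without ties, normal approximation otherwise — the default
#' behaviour of [stats::wilcox.test()]).
#'
#' @param densities Tibble with columns `bin`, `tier`, `class`,
#'   `density`.
#' @param min_per_tier Minimum bins per tier (default 3).
#' @return Tibble: `class`, `tier_a`, `tier_b`, `statistic`, `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_tiers <- function(densities, min_per_tier = 3) {
  tiers <- unique(densities$tier)
  if (length(tiers) < 2) stop("need at least two tiers")
  out <- list()
  for (cls in unique(densities$class)) {
    dc <- densities[densities$class == cls, ]
    for (i in seq_along(tiers)) for (j in seq_along(tiers)) {
      if (i >= j) next
      xa <- dc$density[dc$tier == tiers[i]]
      xb <- dc$density[dc$tier == tiers[j]]
      if (length(xa) < min_per_tier || length(xb) < min_per_tier)
        stop("tier ", tiers[i], " or ", tiers[j], " has fewer than ",
             min_per_tier, " bins for class ", cls)
      wt <- suppressWarnings(stats::wilcox.test(xa, xb))
      out[[length(out) + 1L]] <- tibble::tibble(
        class = cls, tier_a = tiers[i], tier_b = tiers[j],
        statistic = unname(wt$statistic), p_value = wt$p.value,
        n_a = length(xa), n_b = length(xb))
    }
  }
  dplyr::bind_rows(out)
}

#' Flag putative phage scaffolds
#'
#' A scaffold is a putative phage when it is at least 5 kb long and
#' either carries a confident virus-detector category (1, 2 or 4) or a
#' k-mer-model score of at least 0.9 with p < 0.01. The two evidence
#' channels are combined as a union by default; set
#' `combine = "intersection"` to require both.
#'
#' @param length Scaffold lengths in bp.
#' @param category Detector category 1--6, `NA` when absent.
#' @param score K-mer model score in `[0, 1]`, `NA` when absent.
#' @param p_value Matching p-value.
#' @param combine `"union"` (default) or `"intersection"`.
#' @return Logical vector.
#' @export
detect_viral <- function(length, category = NA, score = NA, p_value = NA,
                         combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  cat_ok <- !is.na(category) & category %in% c(1, 2, 4)
  score_ok <- !is.na(score) & !is.na(p_value) & score >= 0.9 & p_value < 0.01
  ev <- if (combine == "union") cat_ok | score_ok else cat_ok & score_ok
  length >= 5000 & ev
}

#' Terminal-overlap circularity test
#'
#' A scaffold assembled from a circular molecule typically carries an
#' identical prefix and suffix. The test reports whether a terminal exact
#' repeat of at least `min_overlap` bp (up to `max_overlap`) exists.
#'
#' @param sequence DNA string.
#' @param min_overlap Minimum overlap length (default 55).
#' @param max_overlap Longest overlap searched (default 1000).
#' @return Logical.
#' @export
is_circular <- function(sequence, min_overlap = 55, max_overlap = 1000) {
  n <- nchar(sequence)
  top <- min(max_overlap, n %/% 2)
  if (top < min_overlap) return(FALSE)
  for (ov in top:min_overlap) {
    if (substr(sequence, 1, ov) == substr(sequence, n - ov + 1, n))
      return(TRUE)
  }
  FALSE
}

#' Flag putative plasmid scaffolds
#'
#' A reconstruction of unbinned-plasmid calling: a scaffold is a putative
#' plasmid when it was not assigned to any bin, exceeds 10 kb and shows
#' circularity evidence (a terminal overlap, or a provided flag).
#'
#' @param length Scaffold lengths in bp.
#' @param binned Logical: scaffold is a member of some bin.
#' @param circular Logical circularity evidence (e.g. from
#'   [is_circular()]).
#' @return Logical vector.
#' @export
detect_plasmid <- function(length, binned, circular) {
  !binned & length > 10000 & circular
}

#' Majority-rule viral taxonomy
#'
#' Discards protein hits with bitscore of 50 or less, then assigns the
#' scaffold to a viral family only when strictly more than half of all
#' its predicted proteins (not just the hit-bearing ones) agree on one
#' family.
#'
#' @param family Character vector of family labels, one per protein hit.
#' @param bitscore Matching bitscores.
#' @param n_proteins Total predicted proteins on the scaffold.
#' @return The family label, or `"unclassified"`.
#' @export
assign_viral_taxonomy <- function(family, bitscore, n_proteins) {
  stopifnot(n_proteins >= 1)
  keep <- bitscore > 50
  if (!any(keep)) return("unclassified")
  counts <- table(family[keep])
  top <- names(counts)[which.max(counts)]
  if (max(counts) / n_proteins > 0.5) top else "unclassified"
}

#' Pathway presence calls
#'
#' A pathway is present in a MAG when strictly more than 66% of its key
#' reactions are identified.
#'
#' @param reactions Character vector of reaction ids found in the MAG.
#' @param pathways Tibble of pathway definitions (`pathway`, `reaction`).
#' @param threshold Fraction of key reactions required (strictly
#'   exceeded; default 0.66).
#' @return Tibble: `pathway`, `n_reactions`, `n_present`, `fraction`,
#'   `present`.
#' @export
pathway_presence <- function(reactions, pathways, threshold = 0.66) {
  if (nrow(pathways) == 0) stop("empty pathway definitions")
  out <- dplyr::group_by(pathways, .data$pathway)
  out <- dplyr::summarise(
    out,
    n_reactions = dplyr::n(),
    n_present = sum(.data$reaction %in% reactions),
    .groups = "drop")
  if (any(out$n_reactions == 0)) stop("pathway with zero key reactions")
  out$fraction <- out$n_present / out$n_reactions
  out$present <- out$fraction > threshold
  out
}

#' Filter functional-annotation hits
#'
#' Database-specific identity/coverage cutoffs: KEGG hits need identity
#' >= 0.30 and query coverage >= 0.70; antibiotic-resistance (CARD) hits
#' need identity >= 0.95 and coverage >= 0.90.
#'
#' @param identity Hit identity fraction(s).
#' @param coverage Query coverage fraction(s).
#' @param database `"kegg"` or `"card"`.
#' @return Logical keep flags.
#' @export
filter_hits <- function(identity, coverage, database) {
  database <- match.arg(tolower(database), c("kegg", "card"))
  if (database == "kegg") identity >= 0.30 & coverage >= 0.70
  else identity >= 0.95 & coverage >= 0.90
}

#' Pathway enrichment between groups
#'
#' One-sided Fisher's exact test (alternative "greater": enrichment in
#' the first group) on a 2x2 presence/absence table per pathway, with
#' Hochberg step-up adjustment across pathways.
#'
#' @param tables Named list of 2x2 integer matrices
#'   (rows: in-group / out-group; columns: present / absent).
#' @return Tibble: `pathway`, `p_value`, `p_adjusted`, sorted as given.
#' @export
enrichment <- function(tables) {
  p <- vapply(tables, function(tb) {
    stopifnot(all(tb >= 0), all(dim(tb) == c(2, 2)))
    stats::fisher.test(tb, alternative = "greater")$p.value
  }, numeric(1))
  tibble::tibble(
    pathway = names(tables) %||% as.character(seq_along(tables)),
    p_value = unname(p),
    p_adjusted = unname(stats::p.adjust(p, method = "hochberg"))
  )
}
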