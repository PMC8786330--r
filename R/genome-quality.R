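#' Marker-based completeness and contamination
#'
#' Completeness is the fraction of the single-copy marker universe seen
#' at least once in the bin; contamination is the number of extra marker
#' copies beyond one per marker, as a fraction of the universe. This is
#' the package's single-copy-gene analogue of lineage-workflow
#' completeness estimators, not a reimplementation of them.
#'
#' @param bin_scaffolds Character vector of member scaffold ids.
#' @param scg Marker hit table from [detect_scg()].
#' @param n_scg Marker universe size (default 123).
#' @return Named numeric vector `c(completeness, contamination)`.
#' @export
scg_completeness <- function(bin_scaffolds, scg, n_scg = 123) {
  h <- scg[scg$scaffold %in% bin_scaffolds, ]
  if (nrow(h) == 0) return(c(completeness = 0, contamination = 0))
  copies <- table(h$marker)
  c(completeness = length(copies) / n_scg,
    contamination = sum(copies - 1L) / n_scg)
}

#' Genome quality score
#'
#' Percent-scale score: 100 x completeness minus 5 times 100 x
#' contamination. A complete, clean genome scores 100; each percent of
#' contamination costs five points.
#'
#' @param completeness,contamination Fractions in `[0, 1]`.
#' @return Numeric score (percent scale), vectorized.
#' @export
#' @examples
#' quality_score(0.90, 0.05)  # 65
quality_score <- function(completeness, contamination) {
  100 * completeness - 5 * (100 * contamination)
}

#' Completeness-adjusted genome size
#'
#' Scales the assembled bin size by the estimated completeness and
#' contamination: `size / (completeness + contamination)`, both as
#' fractions (percent units would shrink the estimate about 100-fold).
#'
#' @param assembly_size Assembled size in bp.
#' @param completeness,contamination Fractions; their sum must be > 0.
#' @return Estimated genome size in bp, vectorized.
#' @export
estimated_genome_size <- function(assembly_size, completeness, contamination) {
  denom <- completeness + contamination
  if (any(denom <= 0)) stop("completeness + contamination must be > 0")
  assembly_size / denom
}

#' MIMAG classification
#'
#' `high-quality` requires completeness above 90%, contamination below
#' 5%, all three rRNA genes (5S, 16S, 23S) and at least 18 tRNAs.
#' Otherwise `draft` when the draft criteria hold (completeness > 80%,
#' contamination < 5%, score > 60), else `fail`.
#'
#' @param completeness,contamination Fractions.
#' @param rrna_5s,rrna_16s,rrna_23s Logical presence flags.
#' @param trna_count tRNA count.
#' @return Character vector in `{high-quality, draft, fail}`, vectorized.
#' @export
classify_mimag <- function(completeness, contamination, rrna_5s, rrna_16s,
                           rrna_23s, trna_count) {
  score <- quality_score(completeness, contamination)
  hq <- completeness > 0.90 & contamination < 0.05 &
    rrna_5s & rrna_16s & rrna_23s & trna_count >= 18
  draft <- completeness > 0.80 & contamination < 0.05 & score > 60
  dplyr::case_when(hq ~ "high-quality", draft ~ "draft", TRUE ~ "fail")
}

#' Fragment-based average nucleotide identity
#'
#' The query is cut into fragments; each fragment is seeded onto the
#' reference by exact k-mer matches, the best-voted diagonal offsets are
#' evaluated by ungapped identity, and a fragment maps when its best
#' identity reaches `min_identity` (both strands tried). ANI is the mean
#' identity over mapped fragments; coverage is the mapped fraction of
#' query fragments.
#'
#' @param query,reference DNA strings (each at least 2 fragments long).
#' @param fragment Fragment length in bp (default 1000).
#' @param k Seed k-mer length (default 16).
#' @param stride Spacing of seed k-mers within a fragment (default 50).
#' @param min_identity Identity below which a fragment does not map
#'   (default 0.8).
#' @return One-row tibble: `ani`, `coverage`, `n_fragments`, `n_mapped`.
#' @export
compute_ani <- function(query, reference, fragment = 1000, k = 16,
                        stride = 50, min_identity = 0.8) {
  nq <- nchar(query); nr <- nchar(reference)
  if (nq == 0 || nr == 0) stop("empty sequence")
  if (nq < 2 * fragment || nr < 2 * fragment)
    stop("sequences must span at least 2 fragments")
  ref_int <- utf8ToInt(toupper(reference))
  ref_kmers <- substring(toupper(reference), 1:(nr - k + 1), k:nr)

  frag_starts <- seq(1, nq - fragment + 1, by = fragment)
  n_frag <- length(frag_starts)
  ident <- rep(NA_real_, n_frag)

  score_frag <- function(fseq) {
    fint <- utf8ToInt(fseq)
    seed_pos <- seq(1, fragment - k + 1, by = stride)
    seeds <- substring(fseq, seed_pos, seed_pos + k - 1)
    hit <- match(seeds, ref_kmers)
    ok <- !is.na(hit)
    if (!any(ok)) return(NA_real_)
    offsets <- hit[ok] - seed_pos[ok]
    cand <- as.integer(names(sort(table(offsets), decreasing = TRUE)))
    cand <- utils::head(cand, 3)
    best <- NA_real_
    for (off in cand) {
      a <- max(1L, 1L - off); b <- min(fragment, nr - off)
      if (b - a + 1 < 0.8 * fragment) next
      id <- mean(fint[a:b] == ref_int[(a + off):(b + off)])
      if (is.na(best) || id > best) best <- id
    }
    best
  }

  q <- toupper(query)
  for (i in seq_len(n_frag)) {
    fseq <- substr(q, frag_starts[i], frag_starts[i] + fragment - 1)
    id <- score_frag(fseq)
    if (is.na(id) || id < min_identity) {
      id_rc <- score_frag(revcomp(fseq))
      if (!is.na(id_rc) && (is.na(id) || id_rc > id)) id <- id_rc
    }
    ident[i] <- id
  }
  mapped <- !is.na(ident) & ident >= min_identity
  tibble::tibble(
    ani = if (any(mapped)) mean(ident[mapped]) else NA_real_,
    coverage = mean(mapped),
    n_fragments = n_frag,
    n_mapped = sum(mapped)
  )
}

#' Species novelty from best ANI hit
#'
#' A genome is `known` when some reference matches it at >= 95% ANI with
#' at least 40% of the query aligned; otherwise (including no hits at
#' all) it is `novel`.
#'
#' @param ani Best-hit ANI fraction (or `NA` / `NULL` for no hit).
#' @param coverage Aligned fraction of the query.
#' @return `"known"` or `"novel"`, vectorized.
#' @export
classify_novelty <- function(ani, coverage) {
  if (is.null(ani) || length(ani) == 0) return("novel")
  ifelse(!is.na(ani) & !is.na(coverage) & ani >= 0.95 & coverage >= 0.40,
         "known", "novel")
}

#' Quality-improvement flag
#'
#' For a genome matched to a known species, flags whether its quality
#' score strictly exceeds the reference genome's.
#'
#' @param query_score,reference_score Percent-scale quality scores.
#' @return Logical, vectorized.
#' @export
quality_improved <- function(query_score, reference_score) {
  query_score > reference_score
}

#' Peak-to-trough coverage ratio
#'
#' Estimates in-situ growth rate as the ratio of read depth near the
#' replication origin to depth near the terminus. Depth at each anchor is
#' the mean over the `frac` fraction of windows circularly nearest to it
#' (a robust local average). The ratio is reported as >= 1: when the
#' trough-anchored depth exceeds the peak-anchored one the ratio is
#' inverted and `flipped` set, so a swapped ori/ter convention cannot
#' produce spurious sub-unity growth rates.
#'
#' @param depth Windowed depth tibble with `depth` and a genome
#'   coordinate column `genome_mid` (as from [simulate_depth()]); at
#'   least 20 windows.
#' @param ori_pos,ter_pos Genome coordinates (bp) of ori and ter, e.g.
#'   from [cumulative_gc_skew()] (`ori_pos` / `ter_pos`).
#' @param genome_length Genome length in bp for circular distance
#'   (default: max `window_end`-like extent of the depth table).
#' @param frac Fraction of windows averaged at each anchor (default
#'   0.05).
#' @return One-row tibble: `ptr`, `ori_depth`, `ter_depth`, `flipped`.
#' @export
estimate_ptr <- function(depth, ori_pos, ter_pos, genome_length = NULL,
                         frac = 0.05) {
  stopifnot(nrow(depth) >= 20)
  if (is.null(genome_length))
    genome_length <- max(depth$genome_mid) +
      stats::median(diff(sort(depth$genome_mid))) / 2
  circ <- function(a, b) pmin(abs(a - b), genome_length - abs(a - b))
  kk <- max(1L, ceiling(frac * nrow(depth)))
  near <- function(anchor) {
    d <- circ(depth$genome_mid, anchor)
    mean(depth$depth[order(d)[seq_len(kk)]])
  }
  peak <- near(ori_pos); trough <- near(ter_pos)
  if (trough <= 0 && peak <= 0) stop("zero depth at both anchors")
  flipped <- trough > peak
  if (flipped) { tmp <- peak; peak <- trough; trough <- tmp }
  if (trough <= 0) stop("zero trough depth: ratio undefined")
  tibble::tibble(ptr = peak / trough, ori_depth = peak, ter_depth = trough,
                 flipped = flipped)
}

#' Per-bin quality report
#'
#' Combines marker-based completeness/contamination, the quality score,
#' assembly statistics, the completeness-adjusted genome size and the
#' MIMAG class for every bin of a binning result.
#'
#' @param binning A `mag_binning` (or a membership tibble `scaffold`,
#'   `bin`).
#' @param features Feature tibble with `scaffold` and `length`.
#' @param scg Marker hit table.
#' @param annotations Optional annotation table (from
#'   [emit_annotations()] or [read_annotations()]) supplying rRNA/tRNA
#'   counts per genome label; without it the rRNA flags are `FALSE` and
#'   tRNA counts 0, and every bin's MIMAG class falls back to the draft
#'   criteria.
#' @param bin_genome Optional named vector mapping bin id to the genome
#'   label whose annotation rows apply (e.g. the majority truth label).
#' @param n_scg Marker universe size.
#' @return Tibble: `bin`, `n_scaffolds`, `size`, `n50`, `completeness`,
#'   `contamination`, `score`, `est_genome_size`, `rrna_5s`, `rrna_16s`,
#'   `rrna_23s`, `trna_count`, `mimag`.
#' @export
bin_quality <- function(binning, features, scg, annotations = NULL,
                        bin_genome = NULL, n_scg = 123) {
  membership <- if (inherits(binning, "mag_binning")) binning$membership
                else binning
  out <- lapply(split(membership$scaffold, membership$bin), function(mem) {
    len <- features$length[match(mem, features$scaffold)]
    cc <- scg_completeness(mem, scg, n_scg)
    st <- assembly_stats(len)
    tibble::tibble(n_scaffolds = length(mem), size = st$total_length,
                   n50 = st$n50,
                   completeness = cc[["completeness"]],
                   contamination = cc[["contamination"]])
  })
  res <- dplyr::bind_rows(out, .id = "bin")
  res$score <- quality_score(res$completeness, res$contamination)
  res$est_genome_size <- ifelse(
    res$completeness + res$contamination > 0,
    res$size / (res$completeness + res$contamination), NA_real_)
  res$rrna_5s <- FALSE; res$rrna_16s <- FALSE; res$rrna_23s <- FALSE
  res$trna_count <- 0L
  if (!is.null(annotations) && !is.null(bin_genome)) {
    for (i in seq_len(nrow(res))) {
      g <- bin_genome[[res$bin[i]]]
      if (is.null(g) || is.na(g)) next
      ann <- annotations[annotations$genome == g, ]
      res$rrna_5s[i] <- any(ann$type == "rRNA_5S")
      res$rrna_16s[i] <- any(ann$type == "rRNA_16S")
      res$rrna_23s[i] <- any(ann$type == "rRNA_23S")
      res$trna_count[i] <- sum(ann$type == "tRNA")
    }
  }
  res$mimag <- classify_mimag(res$completeness, res$contamination,
                              res$rrna_5s, res$rrna_16s, res$rrna_23s,
                              res$trna_count)
  tibble::as_tibble(res)
}
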