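#' Length-weighted mean depth of a MAG
#'
#' The MAG's depth is the average of its member scaffolds' depths
#' weighted by scaffold length: `sum(depth * length) / sum(length)`.
#'
#' @param depths Per-scaffold mean depths.
#' @param lengths Matching scaffold lengths in bp.
#' @return Scalar depth.
#' @export
#' @examples
#' mag_depth(c(10, 20), c(1000, 3000))  # 17.5
mag_depth <- function(depths, lengths) {
  if (length(depths) == 0) stop("empty bin")
  stopifnot(length(depths) == length(lengths))
  sum(depths * lengths) / sum(lengths)
}

#' Relative abundance of MAGs in a sample
#'
#' Normalizes each MAG's recruited bases (depth x size) by the sample's
#' total mapped bases, so the abundance of a MAG is exactly the fraction
#' of sequencing attributable to it and abundances are comparable across
#' samples.
#'
#' @param depth Per-MAG length-weighted mean depths.
#' @param size Per-MAG total sizes in bp.
#' @param total_bases Total mapped bases of the sample (> 0).
#' @return Vector of abundance fractions.
#' @export
relative_abundance <- function(depth, size, total_bases) {
  if (total_bases <= 0) stop("total mapped bases must be > 0")
  depth * size / total_bases
}

#' Abundance tier of a MAG
#'
#' `high` above 1%, `low` for 0.1--1% inclusive at both ends, and
#' `extra-low` strictly below 0.1% relative abundance.
#'
#' @param abundance Abundance fraction(s) in `[0, 1]`.
#' @return Character vector in `{high, low, extra-low}`.
#' @export
#' @examples
#' classify_tier(c(0.02, 0.005, 0.0005))
classify_tier <- function(abundance) {
  stopifnot(all(abundance >= 0), all(abundance <= 1))
  dplyr::case_when(
    abundance > 0.01 ~ "high",
    abundance >= 0.001 ~ "low",
    TRUE ~ "extra-low"
  )
}

#' Expected sequence yield for a species
#'
#' At a given total data size, a species at abundance `a` contributes
#' `total * a` bases; dividing by its genome size gives the expected
#' coverage. A 5 Gbp sample yields only 5 Mbp — about 1x of a typical
#' genome — for a species at 0.1% abundance, which is why low-abundance
#' genomes need ultra-deep sequencing.
#'
#' @param total_bases Total data size in bp (>= 0).
#' @param abundance Relative abundance fraction(s).
#' @param genome_size Optional genome size in bp for the coverage column.
#' @return Tibble `yield` (bp) and, when `genome_size` is given,
#'   `coverage`.
#' @export
#' @examples
#' expected_yield(5e9, 0.001)            # 5 Mbp
expected_yield <- function(total_bases, abundance, genome_size = NULL) {
  stopifnot(all(total_bases >= 0), all(abundance >= 0), all(abundance <= 1))
  out <- tibble::tibble(yield = total_bases * abundance)
  if (!is.null(genome_size)) out$coverage <- out$yield / genome_size
  out
}

#' Detectability of genomes across sequencing amounts
#'
#' A genome counts as detectable at data amount `D` when its expected
#' coverage `D * abundance / size` reaches `min_coverage`. Returns the
#' detectable-genome count (total and per tier) for each data amount; the
#' counts are nondecreasing step functions of the data amount.
#'
#' @param abundance Per-genome abundance fractions.
#' @param genome_size Per-genome sizes in bp.
#' @param data_amounts Data amounts in bp to evaluate.
#' @param min_coverage Coverage threshold (> 0, default 5).
#' @return Tibble: `data_bases`, `n_detectable`, `n_high`, `n_low`,
#'   `n_extra_low`.
#' @export
rarefy_detectability <- function(abundance, genome_size, data_amounts,
                                 min_coverage = 5) {
  stopifnot(min_coverage > 0)
  tier <- classify_tier(abundance)
  out <- lapply(sort(data_amounts), function(D) {
    det <- D * abundance / genome_size >= min_coverage
    tibble::tibble(data_bases = D,
                   n_detectable = sum(det),
                   n_high = sum(det & tier == "high"),
                   n_low = sum(det & tier == "low"),
                   n_extra_low = sum(det & tier == "extra-low"))
  })
  dplyr::bind_rows(out)
}

#' Per-bin abundance table
#'
#' Computes the length-weighted depth, relative abundance and tier for
#' every bin of a binning result from a windowed depth table.
#'
#' @param binning A `mag_binning` or membership tibble.
#' @param depth Windowed depth tibble (`scaffold`, `window_start`,
#'   `window_end`, `depth`).
#' @param features Feature tibble with `scaffold`, `length`.
#' @param total_bases Total mapped bases of the sample.
#' @return Tibble: `bin`, `size`, `depth`, `abundance`, `tier`.
#' @export
abundance_profile <- function(binning, depth, features, total_bases) {
  membership <- if (inherits(binning, "mag_binning")) binning$membership
                else binning
  per_scaf <- dplyr::group_by(depth, .data$scaffold)
  per_scaf <- dplyr::summarise(
    per_scaf,
    mean_depth = stats::weighted.mean(.data$depth,
                                      .data$window_end - .data$window_start),
    .groups = "drop")
  out <- lapply(split(membership$scaffold, membership$bin), function(mem) {
    len <- features$length[match(mem, features$scaffold)]
    dep <- per_scaf$mean_depth[match(mem, per_scaf$scaffold)]
    d <- mag_depth(dep, len)
    tibble::tibble(size = sum(len), depth = d)
  })
  res <- dplyr::bind_rows(out, .id = "bin")
  res$abundance <- relative_abundance(res$depth, res$size, total_bases)
  res$tier <- classify_tier(pmin(res$abundance, 1))
  tibble::as_tibble(res)
}
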