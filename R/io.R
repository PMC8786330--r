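#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    s <- sequences[[nm]]
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    writeLines(c(paste0(">", nm),
                 substring(s, starts, pmin(starts + width - 1, n))), con)
  }
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a simulated community to disk
#'
#' Scaffolds (or whole genomes) go out as FASTA; the truth table, depth
#' table and annotations as TSV; the genome-level truth additionally as
#' a JSON sidecar when jsonlite is available. The marker catalog is
#' written as `markers.tsv`.
#'
#' @param sim A list from [simulate_community()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(sim$scaffolds))
    write_fasta(stats::setNames(sim$scaffolds$sequence,
                                sim$scaffolds$scaffold),
                file.path(dir, "scaffolds.fasta"))
  write_fasta(sim$genomes, file.path(dir, "genomes.fasta"))
  tt <- sim$truth$genomes
  flat <- tt[!vapply(tt, is.list, logical(1))]
  readr::write_tsv(flat, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$truth$markers, file.path(dir, "markers.tsv"))
  readr::write_tsv(sim$depth, file.path(dir, "depth.tsv"))
  readr::write_tsv(sim$annotations, file.path(dir, "annotations.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(flat, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a windowed depth table
#'
#' @param path TSV with columns `scaffold`, `window_start`, `window_end`,
#'   `depth` (extra columns kept).
#' @return Tibble.
#' @export
read_depth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read an aggregated pileup table
#'
#' @param path TSV with columns `scaffold`, `pos`, `ref`, `base`, `mapq`,
#'   `baseq`, `n`.
#' @return Tibble.
#' @export
read_pileup <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read an annotation table
#'
#' @param path TSV as written by [write_community()].
#' @return Tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
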