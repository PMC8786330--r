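# shared fixtures, built once per test run

rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  pg <- gc / 2; pa <- (1 - gc) / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(pa, pg, pg, pa)), collapse = "")
}

# a small community reused across tests (2 genomes, quick to build)
small_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_genomes(community_spec(
        n_genomes = 2, genome_length_range = c(100e3, 110e3),
        gc_range = c(0.38, 0.52), seed = 401))
    cache
  }
})

# aggregated pileup rows for a single site
site_rows <- function(counts, ref = "A", pos = 0L, scaffold = "s1",
                      mapq = 60L, baseq = 37L) {
  tibble::tibble(
    genome = "g", scaffold = scaffold, pos = pos, ref = ref,
    base = names(counts), mapq = mapq, baseq = baseq,
    n = as.integer(unname(counts))
  )
}

# exhaustive single-substitution oracle for one codon, independent of the
# package's opportunity table
codon_oracle <- function(codon, code) {
  ch <- strsplit(codon, "")[[1]]
  ns <- c(nonsynonymous = 0, synonymous = 0)
  for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), ch[p])) {
    mut <- ch; mut[p] <- alt
    mcd <- paste(mut, collapse = "")
    if (code[[mcd]] != "*" && code[[mcd]] == code[[codon]])
      ns["synonymous"] <- ns["synonymous"] + 1
    else ns["nonsynonymous"] <- ns["nonsynonymous"] + 1
  }
  ns
}

# plain translation table for the oracle (independent copy via Biostrings
# when available, else from seqinr-style hardcoding is avoided: use
# Biostrings which is a test-time dependency of the oracle only)
standard_code <- function() {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    gc <- Biostrings::GENETIC_CODE
    stats::setNames(as.character(gc), names(gc))
  } else {
    skip("Biostrings not available for the genetic-code oracle")
  }
}

# circular distance in windows
circ_win_dist <- function(i, j, n) min(abs(i - j), n - abs(i - j))

# adjusted Rand index between two labelings (Hubert & Arabie form)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sa * sb / n2
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# run the full binning pipeline on a simulated community, with truth
# taxonomy labels standing in for homology assignments
bin_pipeline <- function(sim, seed = 1L) {
  feats <- scaffold_features(sim$scaffolds, sim$depth)
  scg <- detect_scg(sim$scaffolds, sim$truth$markers)
  tax <- tibble::tibble(scaffold = sim$scaffolds$scaffold,
                        taxon = sim$scaffolds$genome)
  bn <- cluster_scaffolds(feats, scg, taxonomy = tax, seed = seed)
  list(features = feats, scg = scg, binning = bn,
       quality = bin_quality(bn, feats, scg))
}
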