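#' Specify a synthetic gut community
#'
#' Builds the parameter object consumed by [generate_genomes()] and the
#' rest of the simulation stack. The defaults describe a deeply sequenced
#' stool-like community: 30 mini-genomes with log-normally distributed
#' relative abundances wide enough to span the high (>1%), low (0.1--1%)
#' and extra-low (<0.1%) tiers, genome-specific GC in the gut-typical
#' 0.30--0.62 band, a planted replication-origin GC-skew structure,
#' peak-to-trough coverage ratios between 1.2 and 2.5, and per-genome SNP
#' densities of 0.5--5 per kb under mildly purifying selection.
#'
#' Genome lengths default to 100--180 kb "mini-genomes" rather than full
#' 2--3 Mb bacterial chromosomes: every downstream statistic operates per
#' base or per window, so the scaled-down genomes exercise identical code
#' paths at a fraction of the cost.
#'
#' @param n_genomes Number of genomes in the community.
#' @param genome_length_range Min/max genome length in bp.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   (unnormalized) abundance draws; draws are renormalized to sum to 1.
#' @param gc_range Min/max per-genome GC fraction.
#' @param n_scg Number of planted single-copy marker identifiers.
#' @param total_bases Total sequencing yield in bp shared by the
#'   community in proportion to abundance.
#' @param ptr_range Min/max planted peak-to-trough (ori/ter) coverage ratio.
#' @param snp_density_range Min/max planted SNPs per kb.
#' @param dnds Planted nonsynonymous/synonymous rate ratio, recycled over
#'   genomes (default 0.3, mild purifying selection).
#' @param mge_counts Named integer vector: planted ORFs per MGE class per
#'   genome (classes `transposon`, `plasmid`, `phage`, `other`).
#' @param rrna_counts Named integer vector of planted 5S/16S/23S rRNA
#'   features per genome.
#' @param trna_count Planted tRNA features per genome.
#' @param skew_amplitude Excess of G over C (as a fraction of GC) on the
#'   ori-to-ter replichore; mirrored on the other replichore.
#' @param seed Integer random seed; the same spec and seed reproduce the
#'   community byte for byte.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 30,
                           genome_length_range = c(100e3, 180e3),
                           abundance_meanlog = 0,
                           abundance_sdlog = 1.8,
                           gc_range = c(0.30, 0.62),
                           n_scg = 123,
                           total_bases = 4.5e10,
                           ptr_range = c(1.2, 2.5),
                           snp_density_range = c(0.5, 5),
                           dnds = 0.3,
                           mge_counts = c(transposon = 6L, plasmid = 4L,
                                          phage = 3L, other = 8L),
                           rrna_counts = c(rRNA_5S = 1L, rRNA_16S = 1L,
                                           rRNA_23S = 1L),
                           trna_count = 20L,
                           skew_amplitude = 0.12,
                           seed = 1L) {
  stopifnot(
    n_genomes >= 1,
    length(genome_length_range) == 2, all(genome_length_range > 0),
    diff(genome_length_range) >= 0,
    abundance_sdlog >= 0,
    length(gc_range) == 2, all(gc_range > 0), all(gc_range < 1),
    diff(gc_range) >= 0,
    n_scg > 0,
    total_bases > 0,
    all(ptr_range >= 1), diff(ptr_range) >= 0,
    all(snp_density_range >= 0), diff(snp_density_range) >= 0,
    all(dnds >= 0),
    skew_amplitude >= 0, skew_amplitude < 1
  )
  structure(
    list(n_genomes = as.integer(n_genomes),
         genome_length_range = genome_length_range,
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         gc_range = gc_range,
         n_scg = as.integer(n_scg),
         total_bases = total_bases,
         ptr_range = ptr_range,
         snp_density_range = snp_density_range,
         dnds = rep_len(dnds, n_genomes),
         mge_counts = mge_counts,
         rrna_counts = rrna_counts,
         trna_count = as.integer(trna_count),
         skew_amplitude = skew_amplitude,
         seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec> ", x$n_genomes, " genomes, ",
      round(x$genome_length_range[1] / 1e3), "-",
      round(x$genome_length_range[2] / 1e3), " kb, ",
      x$n_scg, " markers, ", signif(x$total_bases / 1e9, 3),
      " Gbp yield, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# tag length of the planted single-copy markers
.SCG_TAG_LEN <- 60L

# sample `n` bases with the given GC and G-vs-C skew; A and T symmetric
.sample_bases <- function(n, gc, skew) {
  if (n <= 0) return(character(0))
  pg <- gc / 2 * (1 + skew)
  pc <- gc / 2 * (1 - skew)
  pa <- (1 - gc) / 2
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = c(pa, pc, pg, pa))
}

# expected per-base GC of coding sequence whose codons follow the
# background composition conditioned on not being a stop codon (the
# distribution .sanitize_orf converges to)
.coding_gc <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- names(p)
  cods <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  prob <- p[cods$b1] * p[cods$b2] * p[cods$b3]
  name <- paste0(cods$b1, cods$b2, cods$b3)
  sense <- !(name %in% c("TAA", "TAG", "TGA"))
  gc_count <- (cods$b1 %in% c("G", "C")) + (cods$b2 %in% c("G", "C")) +
    (cods$b3 %in% c("G", "C"))
  sum(prob[sense] * gc_count[sense]) / (3 * sum(prob[sense]))
}

# solve for the background GC that makes the genome (tags + coding +
# intergenic) hit the target GC after stop-codon sanitization
.solve_bg_gc <- function(target, frac_coding) {
  stats::uniroot(function(bg)
    frac_coding * .coding_gc(bg) + (1 - frac_coding) * bg - target,
    interval = c(0.02, 0.98), tol = 1e-6)$root
}

# replace in-frame stop codons by random sense codons drawn near the
# background composition; set start/stop codons
.sanitize_orf <- function(chars, gc) {
  nc <- length(chars)
  stopifnot(nc %% 3 == 0, nc >= 6)
  codons <- paste0(chars[seq(1, nc, 3)], chars[seq(2, nc, 3)], chars[seq(3, nc, 3)])
  codons[1] <- "ATG"
  codons[length(codons)] <- "TAA"
  internal <- 2:(length(codons) - 1)
  bad <- internal[codons[internal] %in% c("TAA", "TAG", "TGA")]
  while (length(bad) > 0) {
    b1 <- .sample_bases(length(bad), gc, 0)
    b2 <- .sample_bases(length(bad), gc, 0)
    b3 <- .sample_bases(length(bad), gc, 0)
    codons[bad] <- paste0(b1, b2, b3)
    bad <- internal[codons[internal] %in% c("TAA", "TAG", "TGA")]
  }
  unlist(strsplit(codons, "", fixed = TRUE))
}

#' Generate the community genomes with planted ground truth
#'
#' Draws one circular genome per community member. Each genome carries:
#' a genome-specific GC content (hit to within 1%); a two-replichore GC
#' skew (G-enriched from the origin at position 0 to the terminus at L/2
#' on the forward strand, C-enriched on the way back) so the cumulative
#' GC skew troughs at ori and peaks at ter; every one of the `n_scg`
#' single-copy marker tags planted exactly once; and a dense complement
#' of forward-strand ORFs (ATG start, TAA stop, no internal stop codon)
#' whose coordinates seed the annotation and pileup simulators.
#'
#' All coordinates in the returned truth are 0-based, half-open.
#'
#' @param spec A [community_spec()].
#' @return A list with `genomes` (named character vector of sequences)
#'   and `truth`, an object of class `community_truth`: a list with
#'   `genomes` (one tibble row per genome: `genome`, `abundance`,
#'   `length`, `gc`, `ori`, `ter`, `ptr`, `snp_density`, `dnds`, `tier`,
#'   plus list-columns `scg` and `orfs`), `markers` (tibble `marker`,
#'   `tag`), and the `spec`.
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_genomes

  # community-level draws
  ab <- stats::rlnorm(n, spec$abundance_meanlog, spec$abundance_sdlog)
  ab <- ab / sum(ab)
  lens <- as.integer(round(stats::runif(n, spec$genome_length_range[1],
                                        spec$genome_length_range[2])))
  gcs <- stats::runif(n, spec$gc_range[1], spec$gc_range[2])
  ptrs <- stats::runif(n, spec$ptr_range[1], spec$ptr_range[2])
  dens <- stats::runif(n, spec$snp_density_range[1], spec$snp_density_range[2])
  ids <- sprintf("G%02d", seq_len(n))

  # global marker catalog: unique 60-bp tags at GC 0.5
  markers <- tibble::tibble(
    marker = sprintf("SCG%03d", seq_len(spec$n_scg)),
    tag = replicate(spec$n_scg,
                    paste(sample(c("A", "C", "G", "T"), .SCG_TAG_LEN,
                                 replace = TRUE), collapse = ""))
  )
  stopifnot(!anyDuplicated(markers$tag))
  tag_gc <- mean(vapply(markers$tag, compute_gc, numeric(1)))
  tag_total <- spec$n_scg * .SCG_TAG_LEN

  genomes <- character(n)
  scg_list <- vector("list", n)
  orf_list <- vector("list", n)

  for (g in seq_len(n)) {
    L <- lens[g]
    if (L <= tag_total + 10 * spec$n_scg)
      stop("genome length ", L, " too short to host ", spec$n_scg, " marker tags")
    # compensate target GC so tags (fixed at ~0.5) do not shift the total
    target_adj <- (gcs[g] * L - tag_gc * tag_total) / (L - tag_total)
    if (target_adj <= 0 || target_adj >= 1)
      stop("target GC ", gcs[g], " unreachable after marker-tag compensation")

    # layout: [intergenic][tag][spacer][ORF] units until the genome is full
    pos <- 0L
    scg_rows <- list(); orf_rows <- list()
    m <- 1L; o <- 1L
    while (pos + 735L <= L - 100L) {
      pos <- pos + sample(30:60, 1)
      if (m <= spec$n_scg) {
        scg_rows[[m]] <- c(start = pos, end = pos + .SCG_TAG_LEN)
        pos <- pos + .SCG_TAG_LEN + 15L
        m <- m + 1L
      }
      orf_len <- 3L * sample(100:200, 1)
      orf_rows[[o]] <- c(start = pos, end = pos + orf_len)
      pos <- pos + orf_len
      o <- o + 1L
    }
    if (m <= spec$n_scg)
      stop("genome ", ids[g], " (", L, " bp) could not host all ",
           spec$n_scg, " marker tags; increase genome_length_range")

    # stop-codon sanitization enriches coding GC; pre-correct the
    # background so the assembled genome hits its target GC
    orf_bp <- sum(vapply(orf_rows, function(r) r[["end"]] - r[["start"]],
                         numeric(1)))
    bg_gc <- .solve_bg_gc(target_adj, orf_bp / (L - tag_total))

    ter <- L %/% 2L
    half1 <- .sample_bases(ter, bg_gc, spec$skew_amplitude)
    half2 <- .sample_bases(L - ter, bg_gc, -spec$skew_amplitude)
    chars <- c(half1, half2)

    scg_tbl <- tibble::tibble(
      marker = markers$marker,
      start = vapply(scg_rows, `[[`, integer(1), "start"),
      end = vapply(scg_rows, `[[`, integer(1), "end")
    )
    for (k in seq_len(nrow(scg_tbl)))
      chars[(scg_tbl$start[k] + 1L):scg_tbl$end[k]] <-
        strsplit(markers$tag[k], "", fixed = TRUE)[[1]]

    orf_tbl <- tibble::tibble(
      orf_id = sprintf("%s_orf%04d", ids[g], seq_along(orf_rows)),
      start = vapply(orf_rows, `[[`, integer(1), "start"),
      end = vapply(orf_rows, `[[`, integer(1), "end"),
      strand = "+"
    )
    for (k in seq_len(nrow(orf_tbl))) {
      rng <- (orf_tbl$start[k] + 1L):orf_tbl$end[k]
      chars[rng] <- .sanitize_orf(chars[rng], bg_gc)
    }

    genomes[g] <- paste(chars, collapse = "")
    scg_list[[g]] <- scg_tbl
    orf_list[[g]] <- orf_tbl
  }
  names(genomes) <- ids

  truth_tbl <- tibble::tibble(
    genome = ids,
    abundance = ab,
    length = lens,
    gc = gcs,
    ori = 0L,
    ter = lens %/% 2L,
    ptr = ptrs,
    snp_density = dens,
    dnds = spec$dnds,
    tier = classify_tier(ab),
    scg = scg_list,
    orfs = orf_list
  )
  truth <- structure(list(genomes = truth_tbl, markers = markers, spec = spec),
                     class = "community_truth")
  list(genomes = genomes, truth = truth)
}

#' @export
print.community_truth <- function(x, ...) {
  cat("<community_truth> ", nrow(x$genomes), " genomes, ",
      nrow(x$markers), " markers, tiers: ",
      paste(names(table(x$genomes$tier)), table(x$genomes$tier),
            sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Fragment genomes into scaffolds
#'
#' Cuts each genome sequentially into fragments whose lengths are drawn
#' from the fragment-length model. Fragments concatenated in order
#' reproduce the genome exactly. A trailing remainder shorter than the
#' model minimum is absorbed into the final fragment; a model length
#' exceeding the genome yields a single fragment.
#'
#' @param genomes Named character vector from [generate_genomes()].
#' @param truth The matching `community_truth`.
#' @param min_length,max_length Fragment length bounds in bp (uniform
#'   draw; set equal for fixed-length fragments). Must be >= 500.
#' @param seed Seed for the length draws (default: the spec seed + 1).
#' @return Tibble of scaffold records: `scaffold`, `genome`, `start`,
#'   `end` (0-based, half-open genome coordinates), `length`, `sequence`.
#' @export
fragment_genomes <- function(genomes, truth, min_length = 2000,
                             max_length = 8000, seed = NULL) {
  stopifnot(min_length >= 500, max_length >= min_length)
  if (is.null(seed)) seed <- truth$spec$seed + 1L
  set.seed(seed)
  out <- lapply(names(genomes), function(id) {
    s <- genomes[[id]]
    L <- nchar(s)
    cuts <- integer(0)
    pos <- 0L
    while (pos < L) {
      len <- if (min_length == max_length) min_length
             else sample(min_length:max_length, 1)
      pos <- min(pos + len, L)
      cuts <- c(cuts, pos)
    }
    # absorb a too-short trailing remainder into the previous fragment
    if (length(cuts) >= 2 && (cuts[length(cuts)] - cuts[length(cuts) - 1]) < min_length)
      cuts <- cuts[-(length(cuts) - 1)]
    starts <- c(0L, cuts[-length(cuts)])
    tibble::tibble(
      scaffold = sprintf("%s_s%03d", id, seq_along(cuts)),
      genome = id,
      start = starts,
      end = cuts,
      length = cuts - starts,
      sequence = substring(s, starts + 1L, cuts)
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate windowed read depth
#'
#' Assigns each genome its share of the total sequencing yield in
#' proportion to abundance, so the genome-average depth is
#' `total_bases * abundance / length`. Depth is modulated log-linearly
#' along each replichore from the origin (\eqn{\times \sqrt{PTR}}) to the
#' terminus (\eqn{\div \sqrt{PTR}}), renormalized so the genome mean is
#' exact, and Poisson noise is added at base resolution (the per-window
#' base count is Poisson, divided by the window span).
#'
#' @param truth A `community_truth`.
#' @param scaffolds Optional scaffold table from [fragment_genomes()];
#'   when omitted each genome is treated as a single scaffold named after
#'   itself.
#' @param total_bases Total yield in bp (default: from the spec).
#' @param window Window size in bp (default 1000, must be >= 100).
#' @param seed Seed (default: spec seed + 2).
#' @return Tibble: `scaffold`, `genome`, `window_start`, `window_end`
#'   (scaffold-local, 0-based half-open), `genome_mid` (genome coordinate
#'   of the window midpoint), `depth`.
#' @export
simulate_depth <- function(truth, scaffolds = NULL, total_bases = NULL,
                           window = 1000, seed = NULL) {
  stopifnot(window >= 100)
  if (is.null(total_bases)) total_bases <- truth$spec$total_bases
  stopifnot(total_bases > 0)
  if (is.null(seed)) seed <- truth$spec$seed + 2L
  set.seed(seed)
  tt <- truth$genomes
  if (is.null(scaffolds)) {
    scaffolds <- tibble::tibble(scaffold = tt$genome, genome = tt$genome,
                                start = 0L, end = tt$length,
                                length = tt$length)
  }
  out <- lapply(seq_len(nrow(scaffolds)), function(i) {
    g <- match(scaffolds$genome[i], tt$genome)
    L <- tt$length[g]
    base_depth <- total_bases * tt$abundance[g] / L
    ptr <- tt$ptr[g]
    slen <- scaffolds$end[i] - scaffolds$start[i]
    starts <- seq.int(0L, slen - 1L, by = window)
    ends <- pmin(starts + window, slen)
    mid <- scaffolds$start[i] + (starts + ends) / 2
    # normalized circular distance from ori: 0 at ori, 1 at ter
    d <- pmin(abs(mid - tt$ori[g]), L - abs(mid - tt$ori[g])) / (L / 2)
    mult <- ptr^(0.5 - d)
    if (ptr > 1) mult <- mult / (sqrt(ptr) * (1 - 1 / ptr) / log(ptr))
    lam <- base_depth * mult * (ends - starts)
    tibble::tibble(scaffold = scaffolds$scaffold[i],
                   genome = scaffolds$genome[i],
                   window_start = starts, window_end = ends,
                   genome_mid = mid,
                   depth = stats::rpois(length(lam), lam) / (ends - starts))
  })
  dplyr::bind_rows(out)
}

#' Simulate per-site pileups with planted SNPs
#'
#' Plants variant sites at each genome's `snp_density`; within ORFs the
#' nonsynonymous : synonymous mix of planted changes realizes the planted
#' dN/dS against the genome's enumerated mutational opportunities
#' (a coding change is nonsynonymous with probability
#' `dnds * oppN / (dnds * oppN + oppS)`). Minor-allele read counts are
#' binomial at the planted allele frequency. Each read carries a mapping
#' and base quality: a `qual_fail_frac` fraction draws qualities below
#' the standard filtering cutoffs (mapq 20 / baseq 30) and should be
#' discarded by [filter_observations()].
#'
#' The pileup is returned in aggregated form: one row per
#' (site, base, mapq, baseq) combination with a count column `n`, which
#' downstream filters and the depth-capping subsampler operate on
#' directly.
#'
#' @param genomes Named character vector of genome sequences.
#' @param truth The matching `community_truth`.
#' @param which_genomes Genome ids to simulate (default: all; pileups are
#'   by far the largest simulated object, so restrict when possible).
#' @param mean_depth Mean read depth per site (Poisson), >= 1.
#' @param af_range Planted minor-allele frequency range (uniform draw per
#'   site).
#' @param qual_fail_frac Fraction of reads with sub-cutoff qualities.
#' @param error_rate Per-base sequencing error rate (default 0).
#' @param seed Seed (default: spec seed + 3).
#' @return A list with `pileup` (tibble: `genome`, `scaffold`, `pos`,
#'   `ref`, `base`, `mapq`, `baseq`, `n`) and `planted` (tibble of
#'   planted variants: `genome`, `pos`, `ref`, `alt`, `coding`, `class`,
#'   `freq`).
#' @export
simulate_pileups <- function(genomes, truth, which_genomes = NULL,
                             mean_depth = 50, af_range = c(0.15, 0.5),
                             qual_fail_frac = 0.1, error_rate = 0,
                             seed = NULL) {
  stopifnot(mean_depth >= 1)
  if (is.null(seed)) seed <- truth$spec$seed + 3L
  set.seed(seed)
  tt <- truth$genomes
  if (is.null(which_genomes)) which_genomes <- tt$genome
  opp <- .codon_change_table()

  pl <- list(); planted <- list()
  for (id in which_genomes) {
    g <- match(id, tt$genome)
    seq_chars <- strsplit(genomes[[id]], "", fixed = TRUE)[[1]]
    L <- length(seq_chars)
    orfs <- tt$orfs[[g]]

    # enumerate coding single-nucleotide opportunities (forward strand ORFs)
    cod <- .enumerate_coding_changes(seq_chars, orfs, opp)
    n_snp <- round(tt$snp_density[g] * L / 1000)
    dnds_g <- tt$dnds[g]

    coding_mask <- logical(L)
    if (nrow(orfs) > 0)
      for (k in seq_len(nrow(orfs)))
        coding_mask[(orfs$start[k] + 1L):orfs$end[k]] <- TRUE
    # exclude first/last codon (fixed start/stop) from plantable coding sites
    plantable_coding <- unique(cod$pos)
    noncoding_pos <- which(!coding_mask) - 1L   # 0-based

    frac_coding <- length(plantable_coding) / (length(plantable_coding) + length(noncoding_pos))
    n_cod <- stats::rbinom(1, n_snp, frac_coding)
    n_non <- n_snp - n_cod

    oppN <- sum(cod$class == "nonsynonymous")
    oppS <- sum(cod$class == "synonymous")
    pN <- dnds_g * oppN / (dnds_g * oppN + oppS)
    # plant the class counts at their expectation so the realized
    # nonsynonymous:synonymous mix carries no extra sampling noise
    kN <- round(n_cod * pN); kS <- n_cod - kN
    pick <- function(cls, k) {
      idx <- which(cod$class == cls)
      idx[sample.int(length(idx), k)]
    }
    sel <- cod[c(if (kN > 0) pick("nonsynonymous", kN),
                 if (kS > 0) pick("synonymous", kS)), , drop = FALSE]
    # de-duplicate positions (two changes at one site would be multi-allelic)
    sel <- sel[!duplicated(sel$pos), , drop = FALSE]

    non_pos <- if (n_non > 0) sample(noncoding_pos, min(n_non, length(noncoding_pos)))
               else integer(0)
    non_ref <- seq_chars[non_pos + 1L]
    non_alt <- vapply(non_ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
      USE.NAMES = FALSE)

    pv <- tibble::tibble(
      genome = id,
      pos = c(sel$pos, non_pos),
      ref = c(sel$ref, non_ref),
      alt = c(sel$alt, non_alt),
      coding = c(rep(TRUE, nrow(sel)), rep(FALSE, length(non_pos))),
      class = c(sel$class, rep("noncoding", length(non_pos))),
      freq = stats::runif(nrow(sel) + length(non_pos), af_range[1], af_range[2])
    )
    pv <- pv[order(pv$pos), ]
    planted[[id]] <- pv

    # vectorized pileup over all sites
    depth <- stats::rpois(L, mean_depth)
    alt_n <- integer(L)
    alt_base <- rep(NA_character_, L)
    if (nrow(pv) > 0) {
      i1 <- pv$pos + 1L
      alt_n[i1] <- stats::rbinom(nrow(pv), depth[i1], pv$freq)
      alt_base[i1] <- pv$alt
    }
    ref_n <- depth - alt_n
    if (error_rate > 0) {
      err <- stats::rbinom(L, ref_n, error_rate)
      ref_n <- ref_n - err
      # errors fold into a single wrong base per site for simplicity
      err_base <- vapply(seq_chars, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1),
        USE.NAMES = FALSE)
    } else {
      err <- integer(L); err_base <- rep(NA_character_, L)
    }
    # split each allele's reads into quality-pass and quality-fail
    mk <- function(count, base) {
      fail <- stats::rbinom(L, count, qual_fail_frac)
      pass <- count - fail
      pos0 <- 0:(L - 1)
      dplyr::bind_rows(
        tibble::tibble(pos = pos0, base = base, mapq = 60L, baseq = 37L, n = pass),
        tibble::tibble(pos = pos0, base = base, mapq = 15L, baseq = 22L, n = fail)
      )
    }
    rows <- dplyr::bind_rows(
      mk(ref_n, seq_chars),
      mk(alt_n, ifelse(is.na(alt_base), "A", alt_base)),
      if (error_rate > 0) mk(err, err_base)
    )
    keep <- rows$n > 0 & !is.na(rows$base)
    rows <- rows[keep, ]
    rows$genome <- id
    rows$scaffold <- id
    rows$ref <- seq_chars[rows$pos + 1L]
    pl[[id]] <- rows[, c("genome", "scaffold", "pos", "ref", "base",
                         "mapq", "baseq", "n")]
  }
  list(pileup = dplyr::bind_rows(pl), planted = dplyr::bind_rows(planted))
}

# internal-codon start positions (0-based) of forward-strand ORFs,
# excluding the fixed start and stop codons
.internal_codon_starts <- function(orfs) {
  unlist(lapply(seq_len(nrow(orfs)), function(k) {
    cs <- seq.int(orfs$start[k], orfs$end[k] - 3L, by = 3L)
    cs[-c(1L, length(cs))]
  }), use.names = FALSE)
}

# enumerate all single-nucleotide coding changes of forward-strand ORFs,
# excluding the fixed start and stop codons (fully vectorized: 9 change
# rows per codon via the per-codon change table)
.enumerate_coding_changes <- function(seq_chars, orfs, opp) {
  empty <- tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), class = character(0))
  if (nrow(orfs) == 0) return(empty)
  codon_starts <- .internal_codon_starts(orfs)
  if (length(codon_starts) == 0) return(empty)
  codons <- paste0(seq_chars[codon_starts + 1L],
                   seq_chars[codon_starts + 2L],
                   seq_chars[codon_starts + 3L])
  opp <- opp[order(opp$codon, opp$offset, opp$alt), ]  # 9 rows per codon
  ci <- match(codons, unique(opp$codon))
  flat <- rep((ci - 1L) * 9L, each = 9L) + rep_len(1:9, 9L * length(ci))
  tibble::tibble(pos = rep(codon_starts, each = 9L) + opp$offset[flat],
                 ref = opp$ref[flat], alt = opp$alt[flat],
                 class = opp$class[flat])
}

#' Emit gene annotations with planted MGE keywords and RNA features
#'
#' Formats each genome's planted ORFs as an annotation table. The first
#' `mge_counts[class]` ORFs of each class (taken in genome order after
#' skipping previously claimed ORFs) receive a product description
#' containing a recognized keyword of that class; all remaining ORFs are
#' "hypothetical protein". rRNA and tRNA features are appended with
#' nominal coordinates (their counts, not their positions, feed the
#' MIMAG checks).
#'
#' @param truth A `community_truth`.
#' @param mge_counts,rrna_counts,trna_count Overrides of the spec values.
#' @return Tibble: `genome`, `feature_id`, `type` (`CDS`, `rRNA_5S`,
#'   `rRNA_16S`, `rRNA_23S`, `tRNA`), `start`, `end`, `strand`,
#'   `product`, `mge_class` (planted class or `none`).
#' @export
emit_annotations <- function(truth, mge_counts = NULL, rrna_counts = NULL,
                             trna_count = NULL) {
  spec <- truth$spec
  if (is.null(mge_counts)) mge_counts <- spec$mge_counts
  if (is.null(rrna_counts)) rrna_counts <- spec$rrna_counts
  if (is.null(trna_count)) trna_count <- spec$trna_count
  exemplars <- c(
    transposon = "IS3 family transposase",
    plasmid = "conjugal transfer protein TraG",
    phage = "phage major capsid protein",
    other = "site-specific tyrosine recombinase XerD"
  )
  out <- lapply(seq_len(nrow(truth$genomes)), function(g) {
    id <- truth$genomes$genome[g]
    orfs <- truth$genomes$orfs[[g]]
    n_orf <- nrow(orfs)
    if (sum(mge_counts) > n_orf)
      stop("genome ", id, ": requested ", sum(mge_counts),
           " MGE keyword ORFs but only ", n_orf, " ORFs exist")
    product <- rep("hypothetical protein", n_orf)
    mcls <- rep("none", n_orf)
    at <- 1L
    for (cls in names(mge_counts)) {
      k <- mge_counts[[cls]]
      if (k > 0) {
        idx <- at:(at + k - 1L)
        product[idx] <- exemplars[[cls]]
        mcls[idx] <- cls
        at <- at + k
      }
    }
    cds <- tibble::tibble(genome = id, feature_id = orfs$orf_id,
                          type = "CDS", start = orfs$start, end = orfs$end,
                          strand = orfs$strand, product = product,
                          mge_class = mcls)
    rna <- list()
    for (rt in names(rrna_counts)) {
      k <- rrna_counts[[rt]]
      if (k > 0)
        rna[[rt]] <- tibble::tibble(
          genome = id,
          feature_id = sprintf("%s_%s_%d", id, rt, seq_len(k)),
          type = rt, start = 0L, end = 0L, strand = "+",
          product = sub("rRNA_", "", rt), mge_class = "none")
    }
    trna <- if (trna_count > 0)
      tibble::tibble(genome = id,
                     feature_id = sprintf("%s_tRNA_%d", id, seq_len(trna_count)),
                     type = "tRNA", start = 0L, end = 0L, strand = "+",
                     product = "tRNA", mge_class = "none")
    dplyr::bind_rows(cds, dplyr::bind_rows(rna), trna)
  })
  dplyr::bind_rows(out)
}

#' One-call community simulation
#'
#' Convenience wrapper running [generate_genomes()],
#' [fragment_genomes()], [simulate_depth()] and [emit_annotations()]
#' under one spec.
#'
#' @param spec A [community_spec()].
#' @param fragment Logical: fragment genomes into scaffolds?
#' @inheritParams fragment_genomes
#' @return List with `genomes`, `truth`, `scaffolds`, `depth`,
#'   `annotations`.
#' @export
simulate_community <- function(spec = community_spec(), fragment = TRUE,
                               min_length = 2000, max_length = 8000) {
  gg <- generate_genomes(spec)
  scaffolds <- if (fragment)
    fragment_genomes(gg$genomes, gg$truth, min_length, max_length)
  else NULL
  depth <- simulate_depth(gg$truth, scaffolds)
  list(genomes = gg$genomes, truth = gg$truth, scaffolds = scaffolds,
       depth = depth, annotations = emit_annotations(gg$truth))
}
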