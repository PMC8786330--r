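# standard genetic code, written out so the package carries no sequence-
# analysis dependency on the hot path
.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# all 9 single-nucleotide changes of every sense codon, classified.
# Changes that create a stop codon count as nonsynonymous.
.codon_change_table <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    bases <- c("A", "C", "G", "T")
    sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
    rows <- list()
    for (cd in sense) {
      ch <- strsplit(cd, "", fixed = TRUE)[[1]]
      for (p in 1:3) {
        for (alt in setdiff(bases, ch[p])) {
          mut <- ch; mut[p] <- alt
          mcd <- paste(mut, collapse = "")
          cls <- if (.GENETIC_CODE[[mcd]] == .GENETIC_CODE[[cd]])
            "synonymous" else "nonsynonymous"
          rows[[length(rows) + 1L]] <- list(codon = cd, offset = p - 1L,
                                            ref = ch[p], alt = alt,
                                            class = cls)
        }
      }
    }
    tbl <<- dplyr::bind_rows(rows)
    tbl
  }
})

# per-codon synonymous / nonsynonymous opportunity counts (sums to 9)
.codon_opportunity_table <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    cc <- .codon_change_table()
    agg <- dplyr::count(cc, .data$codon, .data$class)
    wide <- tidyr::pivot_wider(agg, names_from = "class",
                               values_from = "n", values_fill = 0L)
    tbl <<- wide
    tbl
  }
})

#' Mutational opportunity counts of an ORF
#'
#' Enumerates, codon by codon, all 9 possible single-nucleotide changes
#' and classifies each as synonymous or nonsynonymous under the standard
#' genetic code. Changes that create a stop codon count as nonsynonymous.
#' A terminal stop codon is permitted and excluded from the sums; an
#' internal stop codon is an error.
#'
#' @param orf A coding sequence over A/C/G/T, length divisible by 3.
#' @return Named numeric vector `c(nonsynonymous, synonymous)`; the two
#'   entries sum to 9 times the number of sense codons.
#' @export
#' @examples
#' codon_opportunities("ATG")        # 9 nonsynonymous, 0 synonymous
#' codon_opportunities("ATGAAAGGG")  # 23 and 4
codon_opportunities <- function(orf) {
  orf <- toupper(orf)
  n <- nchar(orf)
  if (n %% 3 != 0) stop("ORF length must be divisible by 3")
  if (grepl("[^ACGT]", orf)) stop("ORF contains ambiguous bases")
  codons <- substring(orf, seq(1, n, 3), seq(3, n, 3))
  if (.GENETIC_CODE[codons[length(codons)]] == "*")
    codons <- codons[-length(codons)]
  if (any(.GENETIC_CODE[codons] == "*"))
    stop("ORF contains an internal stop codon")
  opp <- .codon_opportunity_table()
  m <- opp[match(codons, opp$codon), ]
  c(nonsynonymous = sum(m$nonsynonymous), synonymous = sum(m$synonymous))
}

# opportunity counts pooled over all ORFs of a genome (vectorized over
# codons; start/stop codons of each ORF included like any sense codon
# except the terminal stop, mirroring codon_opportunities())
.pooled_opportunities <- function(genome_seq, orfs) {
  seq_chars <- strsplit(toupper(genome_seq), "", fixed = TRUE)[[1]]
  starts <- unlist(lapply(seq_len(nrow(orfs)), function(k) {
    cs <- seq.int(orfs$start[k], orfs$end[k] - 3L, by = 3L)
    cs[-length(cs)]   # drop the terminal stop codon
  }), use.names = FALSE)
  codons <- paste0(seq_chars[starts + 1L], seq_chars[starts + 2L],
                   seq_chars[starts + 3L])
  opp <- .codon_opportunity_table()
  m <- opp[match(codons, opp$codon), ]
  c(nonsynonymous = sum(m$nonsynonymous), synonymous = sum(m$synonymous))
}

#' Quality-filter pileup observations
#'
#' Keeps an observation only when its mapping quality and base quality
#' both reach the cutoffs; reads below either are discarded.
#'
#' @param pileup Aggregated pileup tibble (columns `mapq`, `baseq`, `n`,
#'   as produced by [simulate_pileups()]).
#' @param mapq_min Minimum mapping quality kept (default 20).
#' @param baseq_min Minimum base quality kept (default 30).
#' @return The retained rows.
#' @export
filter_observations <- function(pileup, mapq_min = 20, baseq_min = 30) {
  pileup[pileup$mapq >= mapq_min & pileup$baseq >= baseq_min, , drop = FALSE]
}

#' Cap per-site depth by subsampling
#'
#' Sites deeper than `cap` reads are downsampled to exactly `cap` reads
#' drawn without replacement (a multivariate hypergeometric draw over the
#' site's (base, quality) categories); shallower sites pass unchanged.
#' The draw is seeded and the pileup is put in canonical
#' (scaffold, position) order first, so the same seed reproduces the same
#' subsample regardless of input row order.
#'
#' @param pileup Aggregated pileup tibble (`scaffold`, `pos`, `base`,
#'   `n`, ...).
#' @param cap Maximum reads retained per site (default 40).
#' @param seed Integer seed.
#' @return The capped pileup, rows with `n` = 0 dropped.
#' @export
subsample_site <- function(pileup, cap = 40, seed = 1L) {
  pileup <- pileup[order(pileup$scaffold, pileup$pos, pileup$base,
                         pileup$mapq, pileup$baseq), , drop = FALSE]
  site <- paste(pileup$scaffold, pileup$pos)
  site_f <- factor(site, levels = unique(site))
  site_tot <- as.vector(tapply(pileup$n, site_f, sum))
  over <- site_tot[as.integer(site_f)] > cap
  if (!any(over)) return(pileup)
  set.seed(seed)
  idx <- which(over)                                  # rows needing a draw
  site_ids <- as.integer(droplevels(site_f[idx]))     # 1..K in site order
  K <- max(site_ids)
  rank_in_site <- stats::ave(rep(1L, length(idx)), site_ids, FUN = seq_along)
  total_left <- as.vector(tapply(pileup$n[idx], site_ids, sum))
  draw_left <- rep(as.integer(cap), K)
  n_new <- integer(length(idx))
  # sequential multivariate-hypergeometric draw: one vectorized rhyper
  # call per category rank, across all over-cap sites at once
  for (r in seq_len(max(rank_in_site))) {
    rows <- which(rank_in_site == r)
    s <- site_ids[rows]
    k <- pileup$n[idx[rows]]
    n_new[rows] <- stats::rhyper(length(rows), k, total_left[s] - k,
                                 draw_left[s])
    total_left[s] <- total_left[s] - k
    draw_left[s] <- draw_left[s] - n_new[rows]
  }
  pileup$n[idx] <- n_new
  pileup[pileup$n > 0, , drop = FALSE]
}

#' Per-site depth summary
#'
#' @param pileup Aggregated pileup tibble.
#' @return Tibble `scaffold`, `pos`, `ref`, `depth`.
#' @export
site_depth <- function(pileup) {
  d <- dplyr::group_by(pileup, .data$scaffold, .data$pos, .data$ref)
  dplyr::summarise(d, depth = sum(.data$n), .groups = "drop")
}

#' MAG eligibility for population-genetic analysis
#'
#' A MAG enters SNP and selection analysis only when enough of its genome
#' is deeply covered: at least `site_min` sites with post-filter depth of
#' at least `depth_min` reads.
#'
#' @param site_depths Numeric vector of per-site depths for one MAG (or a
#'   tibble from [site_depth()]).
#' @param depth_min Minimum per-site depth counted (default 20).
#' @param site_min Minimum number of such sites (default 200000).
#' @return Logical flag.
#' @export
eligible_mag <- function(site_depths, depth_min = 20, site_min = 200000) {
  if (is.data.frame(site_depths)) site_depths <- site_depths$depth
  sum(site_depths >= depth_min) >= site_min
}

#' Call SNPs from a capped pileup
#'
#' A site yields a SNP call when, after quality filtering and depth
#' capping, the major allele frequency is below 0.95 and the top minor
#' allele is supported by at least `min_support` reads. Only sites with
#' at least `depth_min` retained reads are callable (and only those count
#' toward the density denominator — see [snp_density()]).
#'
#' @param pileup Capped, filtered aggregated pileup.
#' @param max_major_freq Major-allele frequency strict upper bound for a
#'   call (default 0.95).
#' @param min_support Minimum reads supporting the top minor allele
#'   (default 2).
#' @param depth_min Minimum retained reads for a site to be callable
#'   (default 20).
#' @return A list with `snps` (tibble: `scaffold`, `pos`, `ref`, `major`,
#'   `major_freq`, `minor`, `minor_n`, `depth`) and `eligible_sites`
#'   (count of callable sites, the density denominator).
#' @export
call_snp <- function(pileup, max_major_freq = 0.95, min_support = 2,
                     depth_min = 20) {
  # collapse to per-(site, base) counts with vectorized grouping
  o <- order(pileup$scaffold, pileup$pos, pileup$base)
  scaf <- pileup$scaffold[o]; pos <- pileup$pos[o]
  base <- pileup$base[o]; ref <- pileup$ref[o]; n <- pileup$n[o]
  new_allele <- c(TRUE, scaf[-1] != scaf[-length(scaf)] |
                    pos[-1] != pos[-length(pos)] |
                    base[-1] != base[-length(base)])
  gid <- cumsum(new_allele)
  an <- as.vector(rowsum(n, gid))
  first <- which(new_allele)
  a_scaf <- scaf[first]; a_pos <- pos[first]
  a_base <- base[first]; a_ref <- ref[first]
  # rank alleles within site by count (descending), alphabetic tie-break
  o2 <- order(a_scaf, a_pos, -an, a_base)
  s_new <- c(TRUE, a_scaf[o2][-1] != a_scaf[o2][-length(o2)] |
               a_pos[o2][-1] != a_pos[o2][-length(o2)])
  sid <- cumsum(s_new)
  rank <- stats::ave(rep(1L, length(o2)), sid, FUN = seq_along)
  depth <- as.vector(rowsum(an[o2], sid))
  top1 <- o2[rank == 1L]
  per_site <- tibble::tibble(
    scaffold = a_scaf[top1], pos = a_pos[top1], ref = a_ref[top1],
    depth = depth, major = a_base[top1], major_n = an[top1],
    minor = NA_character_, minor_n = 0L)
  top2 <- o2[rank == 2L]
  has2 <- sid[rank == 2L]
  per_site$minor[has2] <- a_base[top2]
  per_site$minor_n[has2] <- an[top2]
  callable <- per_site[per_site$depth >= depth_min, , drop = FALSE]
  callable$major_freq <- callable$major_n / callable$depth
  snps <- callable[callable$major_freq < max_major_freq &
                     callable$minor_n >= min_support, , drop = FALSE]
  list(
    snps = snps[, c("scaffold", "pos", "ref", "major", "major_freq",
                    "minor", "minor_n", "depth")],
    eligible_sites = nrow(callable)
  )
}

#' SNP density per kilobase
#'
#' @param n_snps Number of SNP calls.
#' @param n_sites Number of eligible (callable) sites.
#' @return SNPs per kb.
#' @export
snp_density <- function(n_snps, n_sites) {
  if (n_sites <= 0) stop("no eligible sites: density undefined")
  1000 * n_snps / n_sites
}

#' Classify SNP calls as synonymous / nonsynonymous / noncoding
#'
#' Locates each SNP within the forward-strand ORFs of its genome,
#' reconstitutes the affected codon from the reference sequence, and
#' classifies the reference-to-minor-allele change under the standard
#' genetic code. SNPs in the fixed start/stop codons or outside ORFs are
#' `noncoding`.
#'
#' @param snps SNP tibble from [call_snp()] (positions 0-based; `scaffold`
#'   must name the genome).
#' @param orfs ORF tibble (`start`, `end` 0-based half-open, forward
#'   strand).
#' @param genome_seq The genome sequence the positions refer to.
#' @return `snps` with an added `class` column.
#' @export
classify_substitutions <- function(snps, orfs, genome_seq) {
  seq_chars <- strsplit(toupper(genome_seq), "", fixed = TRUE)[[1]]
  cls <- rep("noncoding", nrow(snps))
  if (nrow(snps) > 0 && nrow(orfs) > 0) {
    orfs <- orfs[order(orfs$start), ]
    k <- findInterval(snps$pos, orfs$start)
    in_orf <- k >= 1 & snps$pos < orfs$end[pmax(k, 1L)]
    idx <- which(in_orf)
    if (length(idx) > 0) {
      p <- snps$pos[idx]; kk <- k[idx]
      off <- p - orfs$start[kk]
      codon_i <- off %/% 3L
      n_codons <- (orfs$end[kk] - orfs$start[kk]) %/% 3L
      internal <- codon_i > 0L & codon_i < n_codons - 1L
      idx <- idx[internal]
      if (length(idx) > 0) {
        p <- p[internal]; cstart <- orfs$start[kk][internal] +
          3L * codon_i[internal]
        codon <- paste0(seq_chars[cstart + 1L], seq_chars[cstart + 2L],
                        seq_chars[cstart + 3L])
        # the non-reference allele of the call (the minor unless the
        # minor equals the reference base)
        alt <- ifelse(snps$minor[idx] == seq_chars[p + 1L],
                      snps$major[idx], snps$minor[idx])
        cpos <- p - cstart   # 0..2 within codon
        mut <- codon
        substr(mut, cpos + 1L, cpos + 1L) <- alt
        same_aa <- .GENETIC_CODE[mut] != "*" &
          .GENETIC_CODE[mut] == .GENETIC_CODE[codon]
        cls[idx] <- ifelse(same_aa, "synonymous", "nonsynonymous")
      }
    }
  }
  snps$class <- cls
  snps
}

#' pN/pS ratio from classified SNPs
#'
#' The observed nonsynonymous and synonymous polymorphism counts are each
#' normalized by the corresponding mutational opportunity counts pooled
#' over the covered ORFs; the ratio of the two normalized rates is pN/pS.
#' With no synonymous observations the ratio is undefined and flagged.
#'
#' @param obs_n,obs_s Observed nonsynonymous / synonymous SNP counts.
#' @param opp Opportunity vector from [codon_opportunities()] (or the sum
#'   over ORFs).
#' @return One-row tibble: `obs_n`, `obs_s`, `exp_n`, `exp_s`, `pnps`
#'   (NA when undefined), `defined`.
#' @export
pnps <- function(obs_n, obs_s, opp) {
  stopifnot(all(opp > 0))
  defined <- obs_s > 0
  ratio <- if (defined) (obs_n / opp[["nonsynonymous"]]) /
                        (obs_s / opp[["synonymous"]]) else NA_real_
  tibble::tibble(obs_n = obs_n, obs_s = obs_s,
                 exp_n = opp[["nonsynonymous"]], exp_s = opp[["synonymous"]],
                 pnps = ratio, defined = defined)
}

#' Per-MAG population-genetic summary from a pileup
#'
#' Runs the full chain — quality filtering, depth capping, SNP calling,
#' substitution classification, density and pN/pS — for each genome in a
#' pileup.
#'
#' @param pileup Aggregated pileup (from [simulate_pileups()] or
#'   [read_pileup()]).
#' @param truth_orfs Named list of ORF tibbles, one per genome, or a
#'   `community_truth`.
#' @param genomes Named character vector of genome sequences.
#' @param cap,mapq_min,baseq_min,depth_min Filter settings (defaults 40,
#'   20, 30, 20).
#' @param seed Seed for the subsampling draw.
#' @return Tibble: one row per genome with `genome`, `eligible_sites`,
#'   `n_snps`, `snp_density`, `obs_n`, `obs_s`, `pnps`.
#' @export
popgen_profile <- function(pileup, truth_orfs, genomes, cap = 40,
                           mapq_min = 20, baseq_min = 30, depth_min = 20,
                           seed = 1L) {
  if (inherits(truth_orfs, "community_truth"))
    truth_orfs <- stats::setNames(truth_orfs$genomes$orfs,
                                  truth_orfs$genomes$genome)
  out <- lapply(split(pileup, pileup$genome), function(pg) {
    id <- pg$genome[1]
    flt <- filter_observations(pg, mapq_min, baseq_min)
    capped <- subsample_site(flt, cap = cap, seed = seed)
    calls <- call_snp(capped, depth_min = depth_min)
    orfs <- truth_orfs[[id]]
    snps <- classify_substitutions(calls$snps, orfs, genomes[[id]])
    opp <- .pooled_opportunities(genomes[[id]], orfs)
    obs_n <- sum(snps$class == "nonsynonymous")
    obs_s <- sum(snps$class == "synonymous")
    pn <- pnps(obs_n, obs_s, opp)
    tibble::tibble(genome = id,
                   eligible_sites = calls$eligible_sites,
                   n_snps = nrow(snps),
                   snp_density = snp_density(nrow(snps), calls$eligible_sites),
                   obs_n = obs_n, obs_s = obs_s, pnps = pn$pnps)
  })
  dplyr::bind_rows(out)
}

#' Rank correlations between genomic features
#'
#' Spearman correlations, with ties mid-ranked and two-sided p-values
#' from the large-sample t approximation, between every pair of numeric
#' columns — the cross-feature comparison of abundance, SNP density,
#' pN/pS, growth rate, genome size, coding density and GC.
#'
#' @param features Data frame of one row per MAG; non-numeric columns are
#'   dropped. At least 5 complete rows required.
#' @return Object of class `mag_correlations`: tibble `var1`, `var2`,
#'   `rho`, `p_value`, `n`, with the full rho matrix in attribute
#'   `matrix`.
#' @export
feature_correlations <- function(features) {
  num <- features[vapply(features, is.numeric, logical(1))]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(num) < 5) stop("need at least 5 MAGs with complete feature rows")
  vars <- names(num)
  rmat <- matrix(NA_real_, length(vars), length(vars),
                 dimnames = list(vars, vars))
  rows <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    x <- num[[i]]; y <- num[[j]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      rho <- stats::cor(rank(x), rank(y))
      n <- length(x)
      if (abs(rho) >= 1) p <- 0
      else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tstat), n - 2)
      }
    }
    rmat[i, j] <- rho
    if (j > i)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        var1 = vars[i], var2 = vars[j], rho = rho, p_value = p,
        n = nrow(num))
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "matrix") <- rmat
  class(res) <- c("mag_correlations", class(res))
  res
}
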