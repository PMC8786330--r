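test_that("quality filtering keeps mapq >= 20 and baseq >= 30", {
  p <- tibble::tibble(
    genome = "g", scaffold = "s", pos = 0L, ref = "A", base = "A",
    mapq = c(19, 20, 60, 60), baseq = c(40, 30, 29, 37),
    n = c(5L, 5L, 5L, 5L)
  )
  out <- filter_observations(p)
  expect_equal(nrow(out), 2)
  expect_true(all(out$mapq >= 20 & out$baseq >= 30))
})

test_that("depth capping subsamples to exactly 40 and is seeded", {
  deep <- site_rows(c(A = 70L, G = 30L))
  capped <- subsample_site(deep, cap = 40, seed = 3)
  expect_equal(sum(capped$n), 40)
  # proportions roughly preserved (hypergeometric mean 28 / 12)
  expect_gte(capped$n[capped$base == "A"], 20)

  shallow <- site_rows(c(A = 25L, G = 5L))
  expect_equal(subsample_site(shallow, cap = 40, seed = 3)$n, c(25L, 5L))

  again <- subsample_site(deep, cap = 40, seed = 3)
  expect_identical(capped, again)
  shuffled <- subsample_site(deep[2:1, ], cap = 40, seed = 3)
  expect_identical(capped, shuffled)
})

test_that("MAG eligibility needs 200,000 sites of >= 20x", {
  expect_true(eligible_mag(rep(25, 250000)))
  expect_false(eligible_mag(rep(25, 199999)))
  expect_false(eligible_mag(numeric(0)))
  expect_true(eligible_mag(c(rep(19, 1e5), rep(20, 2e5))))
})

test_that("SNP calling applies the 95% major-frequency and 2-read rules", {
  no_call <- call_snp(site_rows(c(A = 38L, G = 2L)))
  expect_equal(nrow(no_call$snps), 0)   # major exactly 0.95
  expect_equal(no_call$eligible_sites, 1)

  call <- call_snp(site_rows(c(A = 37L, G = 3L)))
  expect_equal(nrow(call$snps), 1)
  expect_equal(call$snps$major, "A")
  expect_equal(call$snps$minor, "G")
  expect_equal(call$snps$minor_n, 3L)

  weak <- call_snp(site_rows(c(A = 39L, G = 1L)))
  expect_equal(nrow(weak$snps), 0)

  # sites below the calling floor are neither called nor counted
  thin <- call_snp(site_rows(c(A = 10L, G = 5L)))
  expect_equal(nrow(thin$snps), 0)
  expect_equal(thin$eligible_sites, 0)

  # only the top minor allele is evaluated
  tri <- call_snp(site_rows(c(A = 30L, G = 6L, T = 4L)))
  expect_equal(tri$snps$minor, "G")
})

test_that("SNP density is per kilobase of eligible sites", {
  expect_equal(snp_density(150, 300000), 0.5)
  expect_equal(snp_density(0, 1000), 0)
  expect_error(snp_density(5, 0))
})

test_that("codon opportunities match the exhaustive 9-substitution oracle", {
  code <- standard_code()
  expect_equal(codon_opportunities("ATG"),
               c(nonsynonymous = 9, synonymous = 0))
  expect_equal(codon_opportunities("AAA"),
               c(nonsynonymous = 8, synonymous = 1))
  expect_equal(codon_opportunities("ATGAAAGGG"),
               c(nonsynonymous = 23, synonymous = 4))

  sense <- names(code)[code != "*"]
  for (cd in sense) {
    got <- codon_opportunities(cd)
    want <- codon_oracle(cd, code)
    expect_equal(got[["nonsynonymous"]], want[["nonsynonymous"]],
                 info = cd)
    expect_equal(got[["synonymous"]], want[["synonymous"]], info = cd)
    expect_equal(sum(got), 9, info = cd)
  }

  expect_error(codon_opportunities("ATGA"))
  expect_error(codon_opportunities("ATGNAA"))
  expect_error(codon_opportunities("ATGTAAGGG"), "stop")
  # a terminal stop codon is tolerated and excluded
  expect_equal(codon_opportunities("ATGTAA"),
               c(nonsynonymous = 9, synonymous = 0))
})

test_that("opportunities sum to 3x the coding length", {
  cm <- small_community()
  orfs <- cm$truth$genomes$orfs[[1]][1:10, ]
  for (k in seq_len(nrow(orfs))) {
    orf <- substring(cm$genomes[[1]], orfs$start[k] + 1, orfs$end[k])
    opp <- codon_opportunities(orf)
    expect_equal(sum(opp), 3 * (nchar(orf) - 3))  # minus terminal stop
  }
})

test_that("pN/pS normalizes observed counts by opportunities", {
  opp <- codon_opportunities("ATGAAAGGG")  # 23 N, 4 S
  only_syn <- pnps(0, 1, opp)
  expect_equal(only_syn$pnps, 0)
  expect_true(only_syn$defined)

  undef <- pnps(5, 0, opp)
  expect_false(undef$defined)
  expect_true(is.na(undef$pnps))

  balanced <- pnps(23, 4, opp)
  expect_equal(balanced$pnps, 1)
})

test_that("substitution classification uses the reference codon frame", {
  # one ORF at positions 0..8: ATG AAA GGG plus noncoding tail
  genome <- paste0("ATGAAATAA", "TTTTTTTTTT")
  orfs <- tibble::tibble(orf_id = "o1", start = 0L, end = 9L, strand = "+")
  snps <- tibble::tibble(
    scaffold = "g", pos = c(5L, 3L, 12L), ref = c("A", "A", "T"),
    major = c("A", "A", "T"), major_freq = 0.8,
    minor = c("G", "G", "C"), minor_n = 5L, depth = 40L
  )
  out <- classify_substitutions(snps, orfs, genome)
  # AAA -> AAG synonymous at codon position 3 (pos 5)
  expect_equal(out$class[1], "synonymous")
  # AAA -> GAA nonsynonymous at codon position 1 (pos 3)
  expect_equal(out$class[2], "nonsynonymous")
  # outside any ORF
  expect_equal(out$class[3], "noncoding")
})

test_that("the full popgen chain recovers planted density and selection", {
  sp <- community_spec(n_genomes = 1, genome_length_range = c(120e3, 120e3),
                       snp_density_range = c(2, 2), dnds = 1, seed = 81)
  gg <- generate_genomes(sp)
  pp <- simulate_pileups(gg$genomes, gg$truth, mean_depth = 60)
  prof <- popgen_profile(pp$pileup, gg$truth, gg$genomes, seed = 82)
  L <- gg$truth$genomes$length[1]
  n_planted <- nrow(pp$planted)
  planted_density <- n_planted / (L / 1000)
  se <- sqrt(n_planted) / (L / 1000)
  expect_lt(abs(prof$snp_density - planted_density), 3 * se)
  expect_gt(prof$eligible_sites, 100e3)
})

test_that("density is invariant to depth above the cap", {
  sp <- community_spec(n_genomes = 1, genome_length_range = c(100e3, 100e3),
                       snp_density_range = c(3, 3), seed = 83)
  gg <- generate_genomes(sp)
  d50 <- simulate_pileups(gg$genomes, gg$truth, mean_depth = 50, seed = 1)
  d200 <- simulate_pileups(gg$genomes, gg$truth, mean_depth = 200, seed = 1)
  p50 <- popgen_profile(d50$pileup, gg$truth, gg$genomes, seed = 2)
  p200 <- popgen_profile(d200$pileup, gg$truth, gg$genomes, seed = 2)
  expect_equal(p50$snp_density, p200$snp_density, tolerance = 0.12)
})

test_that("feature correlations match the rank definition", {
  set.seed(90)
  df <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  df$c <- -df$a
  df$d <- df$a + rnorm(30, sd = 0.2)
  res <- feature_correlations(df)
  m <- attr(res, "matrix")
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["a", "c"], -1)
  expect_gt(m["a", "d"], 0.8)

  # agrees with the standard implementation
  ref <- stats::cor(df$a, df$b, method = "spearman")
  expect_equal(m["a", "b"], ref)
  reft <- stats::cor.test(df$a, df$d, method = "spearman", exact = FALSE)
  row <- res[res$var1 == "a" & res$var2 == "d", ]
  expect_equal(row$p_value, reft$p.value, tolerance = 1e-8)

  # constant columns are flagged undefined
  df$e <- 1
  res2 <- feature_correlations(df)
  expect_true(is.na(attr(res2, "matrix")["a", "e"]))

  expect_error(feature_correlations(df[1:3, ]))
})
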