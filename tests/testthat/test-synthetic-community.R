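test_that("the same spec and seed reproduce the community byte for byte", {
  sp <- community_spec(n_genomes = 2, genome_length_range = c(100e3, 105e3),
                       seed = 7)
  a <- generate_genomes(sp)
  b <- generate_genomes(sp)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth$genomes, b$truth$genomes)

  fa <- fragment_genomes(a$genomes, a$truth)
  fb <- fragment_genomes(b$genomes, b$truth)
  expect_identical(fa, fb)

  da <- simulate_depth(a$truth, total_bases = 1e8)
  db <- simulate_depth(b$truth, total_bases = 1e8)
  expect_identical(da, db)
})

test_that("abundances renormalize to exactly 1 and set the tier labels", {
  sp <- community_spec(n_genomes = 3, abundance_sdlog = 0,
                       genome_length_range = c(100e3, 100e3), seed = 2)
  gg <- generate_genomes(sp)
  expect_equal(gg$truth$genomes$abundance, rep(1 / 3, 3))
  expect_equal(sum(gg$truth$genomes$abundance), 1, tolerance = 1e-9)
  expect_true(all(gg$truth$genomes$tier == "high"))
})

test_that("generated genomes hit their target GC within 1%", {
  sp <- community_spec(n_genomes = 2, gc_range = c(0.5, 0.5),
                       genome_length_range = c(100e3, 100e3), seed = 3)
  gg <- generate_genomes(sp)
  for (s in gg$genomes) {
    expect_gte(compute_gc(s), 0.49)
    expect_lte(compute_gc(s), 0.51)
  }
  # and across a GC spread
  cm <- small_community()
  err <- abs(vapply(cm$genomes, compute_gc, numeric(1)) -
               cm$truth$genomes$gc)
  expect_true(all(err < 0.01))
})

test_that("every marker tag is planted exactly once per genome", {
  cm <- small_community()
  sc <- tibble::tibble(scaffold = names(cm$genomes),
                       sequence = unname(cm$genomes))
  hits <- detect_scg(sc, cm$truth$markers)
  tally <- table(hits$scaffold, hits$marker)
  expect_true(all(tally == 1))
  # truth coordinates point at the planted tag
  tt <- cm$truth$genomes
  for (g in seq_len(nrow(tt))) {
    scg <- tt$scg[[g]]
    found <- substring(cm$genomes[[g]], scg$start + 1, scg$end)
    expect_identical(found, cm$truth$markers$tag)
  }
})

test_that("invalid specs are rejected", {
  expect_error(community_spec(genome_length_range = c(-1, 100)))
  expect_error(community_spec(abundance_sdlog = -0.5))
  expect_error(community_spec(n_scg = 0))
  expect_error(community_spec(total_bases = 0))
  # genome too small to host the marker complement
  expect_error(generate_genomes(
    community_spec(n_genomes = 1, genome_length_range = c(20e3, 20e3),
                   seed = 1)), "marker")
})

test_that("fragments reproduce the genome exactly", {
  cm <- small_community()
  # fixed-length fragmentation of an even multiple
  g10 <- substr(cm$genomes[[1]], 1, 10e3)
  truth1 <- cm$truth
  one <- stats::setNames(g10, "G01")
  fr <- fragment_genomes(one, truth1, min_length = 2000, max_length = 2000)
  expect_equal(nrow(fr), 5)
  expect_true(all(fr$length == 2000))
  expect_identical(paste(fr$sequence, collapse = ""), g10)

  # uniform model conserves total length and order
  fr2 <- fragment_genomes(cm$genomes, cm$truth, 2000, 5000)
  for (id in names(cm$genomes)) {
    sub <- fr2[fr2$genome == id, ]
    expect_equal(sum(sub$length), nchar(cm$genomes[[id]]))
    expect_identical(paste(sub$sequence, collapse = ""), cm$genomes[[id]])
  }
  expect_true(all(fr2$length >= 2000))
  expect_error(fragment_genomes(cm$genomes, cm$truth, min_length = 400))
})

test_that("simulated depth matches the closed-form expectation", {
  sp <- community_spec(n_genomes = 2, abundance_sdlog = 0,
                       genome_length_range = c(100e3, 100e3),
                       ptr_range = c(1, 1), seed = 5)
  gg <- generate_genomes(sp)
  # abundance 0.5, total 1 Gbp, genome 100 kb -> expected depth 5000;
  # average the genome mean over replicates to sharpen the check
  exp_depth <- 1e9 * 0.5 / 1e5
  se <- sqrt(exp_depth / 1e5)  # Poisson on the genome's base count
  reps <- 10
  set.seed(42)
  means <- replicate(reps, {
    d <- simulate_depth(gg$truth, total_bases = 1e9,
                        seed = sample.int(1e7, 1))
    tapply(d$depth, d$genome, mean)
  })
  for (id in names(gg$genomes))
    expect_lt(abs(mean(means[id, ]) - exp_depth), 3 * se / sqrt(reps))
  # ptr = 1: flat expected profile, max/min ratio near 1
  d <- simulate_depth(gg$truth, total_bases = 1e9)
  for (id in names(gg$genomes)) {
    dep <- d$depth[d$genome == id]
    expect_lt(stats::sd(dep) / mean(dep), 0.05)
  }
  expect_error(simulate_depth(gg$truth, total_bases = 0))
})

test_that("the planted peak-to-trough ratio shapes the depth profile", {
  sp <- community_spec(n_genomes = 1, genome_length_range = c(120e3, 120e3),
                       ptr_range = c(2, 2), seed = 6)
  gg <- generate_genomes(sp)
  ratios <- replicate(50, {
    d <- simulate_depth(gg$truth, total_bases = 6e6,
                        seed = sample.int(1e6, 1))
    ori_d <- mean(d$depth[d$genome_mid < 3000 | d$genome_mid > 117000])
    ter_d <- mean(d$depth[abs(d$genome_mid - 60000) < 3000])
    ori_d / ter_d
  })
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("pileups plant SNPs at the requested density and dN/dS mix", {
  sp <- community_spec(n_genomes = 1, genome_length_range = c(100e3, 100e3),
                       snp_density_range = c(2, 2), dnds = 1, seed = 8)
  gg <- generate_genomes(sp)
  pp <- simulate_pileups(gg$genomes, gg$truth, mean_depth = 40)
  L <- gg$truth$genomes$length[1]
  n_planted <- nrow(pp$planted)
  expect_equal(n_planted, round(2 * L / 1000), tolerance = 0.1)

  # planted N:S equals the opportunity ratio at dnds = 1 (deterministic
  # class counts, so only rounding separates them)
  orfs <- gg$truth$genomes$orfs[[1]]
  opp <- Reduce(`+`, lapply(seq_len(nrow(orfs)), function(k)
    codon_opportunities(substring(gg$genomes[[1]], orfs$start[k] + 1,
                                  orfs$end[k]))))
  coding <- pp$planted[pp$planted$coding, ]
  expect_equal(sum(coding$class == "nonsynonymous") /
                 sum(coding$class == "synonymous"),
               opp[["nonsynonymous"]] / opp[["synonymous"]],
               tolerance = 0.15)

  # planted alternative differs from the reference at every site
  expect_true(all(pp$planted$ref != pp$planted$alt))

  # zero density -> zero non-reference observations at error rate 0
  sp0 <- community_spec(n_genomes = 1, genome_length_range = c(100e3, 100e3),
                        snp_density_range = c(0, 0), seed = 9)
  g0 <- generate_genomes(sp0)
  p0 <- simulate_pileups(g0$genomes, g0$truth, mean_depth = 10)
  expect_equal(nrow(p0$planted), 0)
  expect_true(all(p0$pileup$base == p0$pileup$ref))

  expect_error(simulate_pileups(gg$genomes, gg$truth, mean_depth = 0.5))
})

test_that("annotations carry the planted MGE keywords and RNA features", {
  cm <- small_community()
  ann <- emit_annotations(cm$truth,
                          mge_counts = c(transposon = 3L, plasmid = 0L,
                                         phage = 2L, other = 0L),
                          rrna_counts = c(rRNA_5S = 1L, rRNA_16S = 1L,
                                          rRNA_23S = 1L),
                          trna_count = 18L)
  for (id in names(cm$genomes)) {
    a <- ann[ann$genome == id, ]
    cls <- classify_cmge(a$product[a$type == "CDS"])
    expect_equal(sum(cls == "transposon"), 3)
    expect_equal(sum(cls == "phage"), 2)
    expect_equal(sum(cls == "plasmid"), 0)
    expect_equal(sum(a$type == "tRNA"), 18)
    expect_true(all(c("rRNA_5S", "rRNA_16S", "rRNA_23S") %in% a$type))
  }
  # zero plants -> zero classifier hits
  ann0 <- emit_annotations(cm$truth,
                           mge_counts = c(transposon = 0L, plasmid = 0L,
                                          phage = 0L, other = 0L))
  expect_true(all(classify_cmge(
    ann0$product[ann0$type == "CDS"]) == "none"))
  # impossible request errors
  expect_error(emit_annotations(cm$truth,
                                mge_counts = c(transposon = 100000L)),
               "ORFs")
})
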