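test_that("cMGE keyword classification follows the fixed priority", {
  expect_equal(classify_cmge("Tn3 family transposase"), "transposon")
  expect_equal(classify_cmge("conjugal transfer protein TraG"), "plasmid")
  expect_equal(classify_cmge("phage major capsid protein"), "phage")
  expect_equal(classify_cmge("site-specific integrase"), "other")
  expect_equal(classify_cmge("hypothetical protein"), "none")
  # priority: a description matching transposon and phage words is
  # classified by the earlier class
  expect_equal(classify_cmge("phage transposase A"), "transposon")
  # case-insensitive
  expect_equal(classify_cmge("PUTATIVE TRANSPOSASE"), "transposon")
})

test_that("MGE density normalizes counts by genome size", {
  expect_equal(mge_density(30, 3e6), 10)
  expect_equal(mge_density(0, 3e6), 0)
  expect_equal(mge_density(c(a = 6, b = 3), 2e6), c(a = 3, b = 1.5))
  expect_error(mge_density(5, 0))
})

test_that("tier comparisons run a rank-sum test per class and pair", {
  set.seed(100)
  dens <- tibble::tibble(
    bin = sprintf("b%02d", 1:20),
    tier = rep(c("high", "low"), each = 10),
    class = "transposon",
    density = c(rnorm(10, 12), rnorm(10, 3))
  )
  res <- compare_tiers(dens)
  expect_equal(nrow(res), 1)
  expect_lt(res$p_value, 0.001)

  # complete separation gives the minimal exact p for these sizes
  sep <- dens
  sep$density <- c(rep(10, 10) + 1:10, rep(0, 10) + 1:10 / 100)
  res2 <- compare_tiers(sep)
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  expect_error(compare_tiers(dens[c(1:10, 11), ]), "fewer than")
})

test_that("viral detection combines length with either evidence channel", {
  expect_true(detect_viral(6000, category = 1))
  expect_true(detect_viral(6000, score = 0.95, p_value = 0.005))
  expect_false(detect_viral(4000, category = 1))
  expect_false(detect_viral(6000, category = 3))
  expect_false(detect_viral(6000, score = 0.89, p_value = 0.005))
  expect_false(detect_viral(6000, score = 0.95, p_value = 0.01))
  # monotone: adding a qualifying category never un-flags
  base_flag <- detect_viral(6000, score = 0.95, p_value = 0.005)
  expect_true(detect_viral(6000, category = 2, score = 0.95,
                           p_value = 0.005) >= base_flag)
  # intersection mode requires both channels
  expect_false(detect_viral(6000, category = 1, combine = "intersection"))
  expect_true(detect_viral(6000, category = 1, score = 0.95,
                           p_value = 0.005, combine = "intersection"))
})

test_that("plasmid calls need unbinned, >10 kb, circular scaffolds", {
  set.seed(101)
  core <- rand_seq(15e3)
  circular <- paste0(core, substr(core, 1, 500))
  linear <- rand_seq(15e3)
  expect_true(is_circular(circular))
  expect_false(is_circular(linear))

  expect_true(detect_plasmid(nchar(circular), binned = FALSE,
                             circular = TRUE))
  expect_false(detect_plasmid(nchar(circular), binned = TRUE,
                              circular = TRUE))
  expect_false(detect_plasmid(9000, binned = FALSE, circular = TRUE))
  expect_false(detect_plasmid(15000, binned = FALSE, circular = FALSE))
})

test_that("viral taxonomy needs a strict majority of all proteins", {
  fam6 <- c(rep("Siphoviridae", 6), rep("Myoviridae", 4))
  expect_equal(assign_viral_taxonomy(fam6, rep(100, 10), 10),
               "Siphoviridae")
  fam5 <- c(rep("Siphoviridae", 5), rep("Myoviridae", 5))
  expect_equal(assign_viral_taxonomy(fam5, rep(100, 10), 10),
               "unclassified")
  # weak hits are discarded before the vote (bitscore must exceed 50)
  expect_equal(assign_viral_taxonomy(fam6, rep(50, 10), 10),
               "unclassified")
  # denominator counts all proteins, not only hits
  expect_equal(assign_viral_taxonomy(rep("Podoviridae", 6),
                                     rep(100, 6), 12),
               "unclassified")
})

test_that("pathway presence needs strictly more than 66% of key reactions", {
  defs <- tibble::tibble(pathway = rep("scfa1", 9),
                         reaction = sprintf("R%03d", 1:9))
  p6 <- pathway_presence(sprintf("R%03d", 1:6), defs)
  expect_true(p6$present)          # 6/9 = 0.667 > 0.66
  p5 <- pathway_presence(sprintf("R%03d", 1:5), defs)
  expect_false(p5$present)         # 5/9 = 0.556
  all9 <- pathway_presence(sprintf("R%03d", 1:9), defs)
  expect_true(all9$present)
  expect_error(pathway_presence("R001", defs[0, ]))
})

test_that("hit filtering applies the per-database cutoffs", {
  expect_true(filter_hits(0.30, 0.70, "kegg"))
  expect_false(filter_hits(0.29, 0.90, "kegg"))
  expect_false(filter_hits(0.35, 0.69, "kegg"))
  expect_true(filter_hits(0.95, 0.90, "card"))
  expect_false(filter_hits(0.94, 0.95, "card"))
  expect_false(filter_hits(0.99, 0.89, "card"))
  expect_error(filter_hits(0.5, 0.5, "pfam"))
})

test_that("enrichment p-values match the hypergeometric closed form", {
  t1 <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  r1 <- enrichment(list(pw = t1))
  expect_equal(r1$p_value, 1 / choose(20, 10), tolerance = 1e-12)

  t2 <- matrix(c(1, 1, 1, 1), 2)
  r2 <- enrichment(list(pw = t2))
  expect_equal(r2$p_value, 5 / 6, tolerance = 1e-12)

  # Hochberg: equal raw p stay equal; adjusted never below raw
  three <- replicate(3, t2, simplify = FALSE)
  names(three) <- c("a", "b", "c")
  r3 <- enrichment(three)
  expect_equal(r3$p_adjusted, r3$p_value)
  expect_true(all(r3$p_adjusted >= r3$p_value - 1e-12))
  expect_error(enrichment(list(bad = matrix(c(-1, 1, 1, 1), 2))))
})

test_that("Hochberg adjustment follows the step-up algebra", {
  p <- c(0.01, 0.04, 0.03, 0.2)
  # step-up from the largest p: adj_i = min over j >= i of (m - j + 1) p_(j)
  srt <- sort(p)
  m <- length(p)
  adj_sorted <- rev(cummin(rev((m - seq_len(m) + 1) * srt)))
  adj_sorted <- pmin(adj_sorted, 1)
  expect_equal(stats::p.adjust(p, "hochberg")[order(p)], adj_sorted)
})

test_that("the shipped synthetic pathway definitions drive presence calls", {
  defs <- readr::read_tsv(system.file("extdata", "synthetic_pathways.tsv",
                                      package = "maglow"),
                          show_col_types = FALSE)
  expect_true(all(c("pathway", "reaction") %in% names(defs)))
  # a MAG carrying 5 of the 6 butyrate reactions: 0.833 > 0.66 -> present
  calls <- pathway_presence(sprintf("RX%04d", 1:5), defs)
  but <- calls[calls$pathway == "butyrate_synthesis_synthetic", ]
  expect_true(but$present)
  expect_false(any(calls$present[calls$pathway != but$pathway]))
})

test_that("planted MGE counts are recovered exactly through the classifier", {
  cm <- small_community()
  counts <- c(transposon = 4L, plasmid = 2L, phage = 5L, other = 1L)
  ann <- emit_annotations(cm$truth, mge_counts = counts)
  cds <- ann[ann$type == "CDS" & ann$genome == "G01", ]
  cls <- classify_cmge(cds$product)
  expect_equal(as.vector(table(factor(cls, names(counts)))),
               as.vector(counts))
  # density uses the genome size
  dens <- mge_density(sum(cls == "phage"), cm$truth$genomes$length[1])
  expect_equal(dens, 5e6 / cm$truth$genomes$length[1])
})
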