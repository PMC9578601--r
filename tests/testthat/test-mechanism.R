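# Coverage profiles, mechanism calls and neighbour-gene correlation.

test_that("coverage of an empty window is all zero", {
  g <- tiny_genome(1L, seed = 71)
  d <- sample_design("s", "d", "blood", expression = c(pv01 = 0),
                     library_size = 0L, seed = 1)
  sim <- simulate_reads(g, d)
  pr <- coverage_profile(sim$records, g$annotation, "pv01")
  expect_true(all(pr$depth == 0L))
  expect_equal(pr$n_reads, 0L)
  expect_error(coverage_profile(sim$records, g$annotation, "nope"),
               "not in annotation")
})

test_that("profiles use primary alignments only and match read counts", {
  g <- tiny_genome(2L, divergence = 0, seed = 72)
  d <- sample_design("s", "d", "blood", expression = c(pv01 = 1, pv02 = 0),
                     library_size = 500L, error_rate = 0, seed = 3)
  sim <- simulate_reads(g, d)
  pr <- coverage_profile(sim$records, g$annotation, "pv01")
  # every read is duplicated at pv02 as secondary; primaries only here
  expect_equal(pr$n_reads, sum(sim$truth$pos >= pr$window_start &
                                 sim$truth$pos <= pr$window_end))
  pr2 <- coverage_profile(sim$records, g$annotation, "pv02")
  expect_equal(pr2$n_reads, 0L)
})

test_that("the three generator mechanisms are called correctly", {
  specs <- list(
    provirus_spec("own_ltr", "chr1", 8000L),
    provirus_spec("solo_drv", "chr1", 40000L, ltr_subtype = "LTR5B",
                  upstream_driver_offset = 551L),
    provirus_spec("rthru", "chr1", 70000L, has_5ltr = FALSE,
                  mechanism = "read_through"))
  g <- build_genome(specs, seed = 9)
  d <- sample_design("s1", "d1", "testis",
                     expression = c(own_ltr = 1, solo_drv = 1, rthru = 1),
                     library_size = 30000L, seed = 2)
  sim <- simulate_reads(g, d)
  calls <- do.call(rbind, lapply(specs, function(sp) {
    pr <- coverage_profile(sim$records, g$annotation, sp$locus_id)
    classify_mechanism(pr, g$annotation, expressed = TRUE)
  }))
  expect_equal(calls$call, c("ltr_driven", "ltr_driven", "read_through"))
  expect_equal(calls$driver[1], "5ltr")
  expect_equal(calls$driver[2], "solo_drvHS")
  expect_equal(calls$driver[3], "upstream_transcript")
})

test_that("unexpressed loci are silent without threshold evaluation", {
  g <- tiny_genome(1L, seed = 73)
  d <- sample_design("s", "d", "blood", expression = c(pv01 = 0),
                     library_size = 0L, seed = 1)
  sim <- simulate_reads(g, d)
  pr <- coverage_profile(sim$records, g$annotation, "pv01")
  call <- classify_mechanism(pr, g$annotation, expressed = FALSE)
  expect_equal(call$call, "silent")
  expect_true(is.na(call$start_enrichment))
})

test_that("a co-driven provirus correlates strongly with its host gene", {
  specs <- list(
    provirus_spec("pv", "chr1", 30000L, has_5ltr = FALSE,
                  mechanism = "read_through"),
    host_gene_spec("driver", "chr1", 24000L, length = 5000L),
    host_gene_spec("indep", "chr1", 60000L, length = 5000L))
  g <- build_genome(specs, seed = 14)
  ds <- lapply(1:10, function(i) {
    a <- withr::with_seed(1000L + i, stats::rlnorm(2, 0, 0.6))
    sample_design(sprintf("s%02d", i), sprintf("d%02d", i), "blood",
                  expression = c(pv = 0.5 * a[1], driver = a[1],
                                 indep = a[2]),
                  library_size = 4000L, seed = 2000L + i)
  })
  sims <- stats::setNames(lapply(ds, function(d)
    simulate_reads(g, d)$records),
    vapply(ds, `[[`, "", "sample_id"))
  em <- quantify_cohort(sims, g$annotation, emit_metadata(ds))
  corr <- neighbor_gene_correlation(em, window = 10000L)
  drv <- corr[corr$gene == "driver", ]
  expect_gt(drv$r, 0.9)
  expect_lt(drv$p_adj, 0.05)
  # provirus inside the gene interval would be flagged; here adjacent
  expect_false(drv$contained)
})

test_that("intron containment is flagged by interval arithmetic", {
  ann <- data.frame(
    locus_id = c("pv", "gene"), chrom = "chr1",
    start = c(12000L, 10000L), end = c(14000L, 20000L), strand = "+",
    class = c("provirus", "host_gene"), length = c(2001L, 10001L),
    stringsAsFactors = FALSE)
  tpm <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8.5), 2, 4, byrow = TRUE,
                dimnames = list(c("pv", "gene"), sprintf("s%d", 1:4)))
  em <- structure(list(tpm = tpm, counts = tpm, lengths = ann$length,
                       annotation = ann,
                       metadata = data.frame(sample = colnames(tpm),
                                             tissue = "t"),
                       tpm_universe = "all"),
                  class = "expression_matrix")
  corr <- neighbor_gene_correlation(em)
  expect_true(corr$contained[1])
  expect_gt(corr$r[1], 0.99)
})

test_that("constant vectors give NA correlation with a warning", {
  ann <- data.frame(
    locus_id = c("pv", "gene"), chrom = "chr1",
    start = c(12000L, 10000L), end = c(14000L, 20000L), strand = "+",
    class = c("provirus", "host_gene"), length = c(2001L, 10001L),
    stringsAsFactors = FALSE)
  tpm <- matrix(c(1, 1, 1, 1, 2, 4, 6, 8), 2, 4, byrow = TRUE,
                dimnames = list(c("pv", "gene"), sprintf("s%d", 1:4)))
  em <- structure(list(tpm = tpm, counts = tpm, lengths = ann$length,
                       annotation = ann,
                       metadata = data.frame(sample = colnames(tpm),
                                             tissue = "t"),
                       tpm_universe = "all"),
                  class = "expression_matrix")
  expect_warning(corr <- neighbor_gene_correlation(em), "constant")
  expect_true(is.na(corr$r[1]))
})

test_that("null gene-provirus correlation p-values are roughly uniform", {
  set.seed(77)
  p <- replicate(300, stats::cor.test(rnorm(12), rnorm(12))$p.value)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})
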