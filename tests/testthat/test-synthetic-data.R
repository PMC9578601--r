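# The genome builder and read simulator: planted truth, lesions,
# divergence, metadata and determinism.

test_that("a lesion-free baseline spec reproduces the template byte-for-byte", {
  g <- build_genome(list(provirus_spec("pv", "chr1", 6000L,
                                       ltr_subtype = "LTR5HS")),
                    divergence = 0, ltr_private_divergence = 0, seed = 1)
  expect_identical(locus_sequence(g, "pv"), hml2_template()$sequence)
})

test_that("lesion application tracks template coordinates", {
  s <- "ACGGCCGGTT"
  res <- apply_lesions(s, list(lesion("deletion", 3, 2)))
  expect_identical(res$sequence, "ACCCGGTT")
  expect_identical(res$tpos, c(1L, 2L, 5L, 6L, 7L, 8L, 9L, 10L))
  res2 <- apply_lesions(s, list(lesion("insertion", 5, "AA")))
  expect_identical(res2$sequence, "ACGGCAACGGTT")
  expect_true(all(is.na(res2$tpos[6:7])))
  res3 <- apply_lesions(s, list(lesion("duplication", 3, 4)))
  expect_identical(res3$sequence, "ACGGCCGGCCGGTT")
  expect_error(apply_lesions(s, list(lesion("deletion", 9, 5))),
               "outside the template")
})

test_that("overlapping loci are rejected naming the pair", {
  specs <- list(provirus_spec("a", "chr1", 1000L),
                provirus_spec("b", "chr1", 5000L))
  expect_error(build_genome(specs, seed = 1), "overlapping loci.*a.*b")
})

test_that("same-template proviruses diverge by the configured amount", {
  g <- tiny_genome(2L, seed = 42L, divergence = 0.02)
  a <- strsplit(locus_sequence(g, "pv01"), "")[[1]]
  b <- strsplit(locus_sequence(g, "pv02"), "")[[1]]
  ident <- mean(a == b)
  expect_gt(ident, 0.975)
  expect_lt(ident, 0.985)
})

test_that("make_type1 shortens by exactly 292 nt and refuses re-application", {
  sp <- provirus_spec("x", "chr1", 6000L)
  sp1 <- make_type1(sp)
  expect_equal(sp1$type, 1L)
  expect_error(make_type1(sp1), "already type 1")
  g2 <- build_genome(list(sp1), divergence = 0, seed = 1)
  expect_equal(nchar(locus_sequence(g2, "x")),
               nchar(hml2_template()$sequence) - 292L)
})

test_that("type 1 proviruses lose env and rec but keep np9 extractable", {
  sp1 <- make_type1(provirus_spec("x", "chr1", 6000L))
  g <- build_genome(list(sp1), seed = 7)
  rep <- orf_report(stats::setNames(list(locus_sequence(g, "x")), "x"),
                    types = c(x = 1L))
  expect_false(rep$intact[rep$gene == "env"])
  expect_false(rep$intact[rep$gene == "rec"])
  expect_false(rep$expressible[rep$gene == "env"])
  expect_true(rep$intact[rep$gene == "np9"])
})

test_that("an upstream driver solo LTR is planted at the exact offset", {
  g <- build_genome(list(provirus_spec("pv", "chr1", 20000L,
                                       upstream_driver_offset = 551L)),
                    seed = 3)
  ann <- g$annotation
  solo <- ann[ann$class == "solo_LTR", ]
  expect_equal(nrow(solo), 1L)
  expect_equal(solo$ltr_subtype, "LTR5HS")
  pv <- ann[ann$locus_id == "pv", ]
  expect_equal(pv$start - solo$end, 551L)
})

test_that("zero-abundance and zero-library edge cases behave", {
  g <- tiny_genome(1L)
  d0 <- sample_design("s", "d", "blood", expression = c(pv01 = 0),
                      library_size = 0L, seed = 1)
  sim <- simulate_reads(g, d0)
  expect_equal(nrow(sim$records), 0L)
  d1 <- sample_design("s", "d", "blood", expression = c(pv01 = 0),
                      library_size = 100L, seed = 1)
  expect_error(simulate_reads(g, d1), "total abundance is zero")
  d2 <- sample_design("s", "d", "blood", expression = c(nope = 1),
                      library_size = 10L, seed = 1)
  expect_error(simulate_reads(g, d2), "unknown locus")
})

test_that("reads from one of two identical loci map to both", {
  g <- tiny_genome(2L, divergence = 0, seed = 5)
  d <- sample_design("s", "d", "blood", expression = c(pv01 = 1, pv02 = 0),
                     library_size = 400L, error_rate = 0, seed = 2)
  sim <- simulate_reads(g, d)
  per_read <- table(sim$records$qname)
  expect_true(all(per_read >= 2L))
  # and the primary record is always the true source
  prim <- sim$records[bitwAnd(sim$records$flag, 256L) == 0L, ]
  expect_true(all(prim$qname == sim$truth$read[match(prim$qname,
                                                     sim$truth$read)]))
  expect_true(all(sim$truth$locus == "pv01"))
  m <- match(sim$truth$read, prim$qname)
  expect_identical(prim$pos[m], sim$truth$pos)
})

test_that("read counts follow abundance x length proportions", {
  g <- tiny_genome(2L, seed = 8)
  d <- sample_design("s", "d", "blood", expression = c(pv01 = 2, pv02 = 1),
                     library_size = 3000L, seed = 4)
  sim <- simulate_reads(g, d)
  n1 <- sum(sim$truth$locus == "pv01")
  # equal unit lengths: expect 2000 within 3 binomial standard deviations
  sd3 <- 3 * sqrt(3000 * (2 / 3) * (1 / 3))
  expect_lt(abs(n1 - 2000), sd3)
})

test_that("replicate seeds converge to abundance x length proportions (chi-square)", {
  g <- tiny_genome(3L, seed = 12)
  ab <- c(pv01 = 3, pv02 = 2, pv03 = 1)
  tot <- integer(3)
  for (s in 1:10) {
    d <- sample_design("s", "d", "blood", expression = ab,
                       library_size = 2000L, seed = 100L + s)
    sim <- simulate_reads(g, d)
    tot <- tot + tabulate(factor(sim$truth$locus, names(ab)), 3L)
  }
  gof <- stats::chisq.test(tot, p = ab / sum(ab))
  expect_gt(gof$p.value, 0.01)
})

test_that("fixed seed gives bit-identical FASTA, SAM and TSV outputs", {
  run_once <- function(dir) {
    dir.create(dir, showWarnings = FALSE)
    g <- tiny_genome(2L, seed = 77)
    write_genome_fasta(g, file.path(dir, "g.fasta"))
    write_annotation(g$annotation, file.path(dir, "ann.tsv"))
    d <- sample_design("s", "d", "blood", expression = c(pv01 = 1, pv02 = 1),
                       library_size = 500L, seed = 9)
    simulate_reads(g, d, sam_path = file.path(dir, "s.sam"),
                   truth_path = file.path(dir, "t.tsv"))
    emit_metadata(list(d), file.path(dir, "md.tsv"))
  }
  d1 <- tempfile(); d2 <- tempfile()
  run_once(d1); run_once(d2)
  for (f in c("g.fasta", "ann.tsv", "s.sam", "t.tsv", "md.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
})

test_that("metadata derives the published age bins and rejects bad values", {
  mk <- function(age, hardy = 2L, id = "s1")
    sample_design(id, "d", "blood", age = age, hardy = hardy,
                  expression = c(x = 1))
  md <- emit_metadata(list(mk(30), mk(35, id = "s2"), mk(36, id = "s3"),
                           mk(51, id = "s4"), mk(52, id = "s5"),
                           mk(70, id = "s6")))
  expect_equal(md$age_group,
               c("20-35", "20-35", "35-51", "35-51", "52-70", "52-70"))
  expect_error(mk(19), "age")
  expect_error(mk(71), "age")
  expect_error(mk(30, hardy = 5L), "hardy")
  expect_error(emit_metadata(list(mk(30), mk(40))), "duplicate sample_id")
})
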