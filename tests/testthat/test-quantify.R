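# The EM reassignment quantifier, TPM normalisation and expression
# calling.

test_that("load_alignments groups candidates and pools background", {
  g <- tiny_genome(2L, seed = 30)
  d <- sample_design("s", "d", "blood", expression = c(pv01 = 1, pv02 = 1),
                     library_size = 300L, seed = 2)
  sim <- simulate_reads(g, d)
  aln <- load_alignments(sim$records, g$annotation, "s")
  expect_s3_class(aln, "alignment_set")
  expect_equal(aln$n_reads, 300L)
  expect_true(all(aln$candidates$locus %in%
                    c("pv01", "pv02", "background")))
  # single-record reads have exactly one candidate
  tab <- table(aln$candidates$read)
  expect_true(all(tab >= 1L))
})

test_that("empty SAM yields an empty set and all-zero counts", {
  g <- tiny_genome(1L)
  d <- sample_design("s", "d", "blood", expression = c(pv01 = 0),
                     library_size = 0L, seed = 1)
  path <- tempfile(fileext = ".sam")
  simulate_reads(g, d, sam_path = path)
  counts <- quantify_sample(path, g$annotation)
  expect_equal(sum(counts), 0)
  expect_named(counts, sort(g$annotation$locus_id))
})

test_that("unique reads give raw counts at once, for any prior", {
  aln <- manual_alignment_set(
    read = sprintf("r%d", 1:6),
    locus = c("A", "A", "A", "A", "B", "B"),
    score = rep(0, 6))
  for (prior in c(0, 1, 10)) {
    st <- reassign_em(aln, prior_weight = prior)
    expect_equal(unname(st$counts[c("A", "B")]), c(4, 2), tolerance = 1e-9)
  }
})

test_that("ambiguous reads collapse onto the dominant locus (ML fixed point)", {
  # 10 reads unique to A, 5 ambiguous A/B with equal weights: the ML
  # fixed point assigns all ambiguity to A (degenerate attractor,
  # confirmed by the grid-search oracle below)
  aln <- manual_alignment_set(
    read = c(sprintf("u%02d", 1:10), rep(sprintf("m%d", 1:5), each = 2)),
    locus = c(rep("A", 10), rep(c("A", "B"), 5)),
    score = rep(0, 20))
  st <- reassign_em(aln, prior_weight = 0, tol = 1e-10, max_iter = 10000)
  expect_equal(unname(st$counts["A"]), 15, tolerance = 1e-3)
  expect_equal(unname(st$counts["B"]), 0, tolerance = 1e-3)
  oracle <- grid_search_pi(q_by_read_of(aln), K = 2L)
  expect_equal(unname(oracle["A"]), 1, tolerance = 2e-3)
})

test_that("pure symmetric ambiguity splits 50/50", {
  aln <- manual_alignment_set(
    read = rep(sprintf("m%d", 1:8), each = 2),
    locus = rep(c("A", "B"), 8),
    score = rep(0, 16))
  st <- reassign_em(aln)
  expect_equal(unname(st$counts["A"]), 4, tolerance = 1e-6)
  expect_equal(unname(st$counts["B"]), 4, tolerance = 1e-6)
})

test_that("EM conserves reads and never decreases the log-likelihood", {
  set.seed(99)
  for (case in 1:10) {
    n <- sample(5:30, 1)
    K <- sample(2:4, 1)
    loci <- LETTERS[seq_len(K)]
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(seq_len(K), 1)
      data.frame(read = sprintf("r%02d", i),
                 locus = sample(loci, k),
                 score = round(stats::runif(k, -18, 0)))
    })
    cand <- do.call(rbind, rows)
    aln <- manual_alignment_set(cand$read, cand$locus, cand$score)
    st <- reassign_em(aln)
    expect_equal(sum(st$counts), n, tolerance = 1e-9)
    expect_true(all(diff(st$log_likelihood) > -1e-9))
  }
})

test_that("converged proportions match the simplex grid-search oracle", {
  set.seed(123)
  for (case in 1:8) {
    n <- sample(6:20, 1)
    K <- sample(2:3, 1)
    loci <- LETTERS[seq_len(K)]
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(seq_len(K), 1)
      data.frame(read = sprintf("r%02d", i), locus = sample(loci, k),
                 score = round(stats::runif(k, -12, 0), 1))
    })
    cand <- do.call(rbind, rows)
    # ensure every locus appears
    cand <- rbind(cand, data.frame(read = paste0("fix", seq_len(K)),
                                   locus = loci, score = 0))
    aln <- manual_alignment_set(cand$read, cand$locus, cand$score)
    st <- reassign_em(aln, tol = 1e-9, max_iter = 20000)
    oracle <- grid_search_pi(q_by_read_of(aln), K = K)
    expect_lt(max(abs(st$pi[loci] - oracle[loci])), 2e-3)
  }
})

test_that("TPM normalises by length and library size", {
  # single feature: any positive count gives 1e6
  expect_equal(counts_to_tpm(matrix(5), 100)[1], 1e6)
  # hand-evaluated: counts (10, 30), lengths (1000, 3000) -> equal rates
  tpm <- counts_to_tpm(matrix(c(10, 30), ncol = 1), c(1000, 3000))
  expect_equal(as.numeric(tpm), c(5e5, 5e5))
  # scale invariance: doubling counts leaves the column unchanged
  m <- matrix(c(3, 7, 11), ncol = 1)
  expect_equal(counts_to_tpm(2 * m, c(100, 200, 300)),
               counts_to_tpm(m, c(100, 200, 300)))
  # every column sums to 1e6
  set.seed(1)
  m2 <- matrix(rpois(20, 50), 5)
  expect_equal(colSums(counts_to_tpm(m2, c(1, 2, 3, 4, 5) * 100)),
               rep(1e6, 4), ignore_attr = TRUE)
  # all-zero sample: zero column with a warning, no NaN
  expect_warning(z <- counts_to_tpm(matrix(0, 2, 1), c(10, 20)),
                 "all-zero")
  expect_equal(as.numeric(z), c(0, 0))
})

test_that("expression calling uses tissue-mean TPM with a closed threshold", {
  tpm <- matrix(c(0.99, 0.99, 1.0, 1.0, 0.2, 5.0), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  md <- data.frame(sample = c("s1", "s2"), tissue = c("t1", "t1"))
  calls <- call_expressed(tpm, md, threshold = 1)
  expect_false(calls$expressed["a", "t1"])   # mean 0.99 < 1
  expect_true(calls$expressed["b", "t1"])    # mean exactly 1.0
  expect_true(calls$expressed["c", "t1"])    # mean 2.6
  # threshold 0: anything with signal is expressed
  calls0 <- call_expressed(tpm, md, threshold = 0)
  expect_true(all(calls0$expressed))
})

test_that("cohort quantification attaches metadata and supports both TPM universes", {
  g <- tiny_genome(2L, seed = 31)
  ds <- lapply(1:3, function(i)
    sample_design(sprintf("s%d", i), sprintf("d%d", i), "blood",
                  expression = c(pv01 = 2, pv02 = 1),
                  library_size = 400L, seed = i))
  sims <- lapply(ds, function(d) simulate_reads(g, d)$records)
  names(sims) <- sprintf("s%d", 1:3)
  md <- emit_metadata(ds)
  em_all <- quantify_cohort(sims, g$annotation, md, tpm_universe = "all")
  em_h <- quantify_cohort(sims, g$annotation, md, tpm_universe = "hml2")
  expect_equal(colSums(em_all$tpm), rep(1e6, 3), ignore_attr = TRUE)
  pv <- rownames(em_h$tpm)
  expect_equal(colSums(em_h$tpm), rep(1e6, 3), ignore_attr = TRUE)
  expect_s3_class(em_all, "expression_matrix")
})
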