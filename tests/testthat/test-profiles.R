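# Tissue patterns, ESA breakdowns and covariate tests.

make_em <- function(tpm, metadata, ann = NULL) {
  if (is.null(ann))
    ann <- data.frame(locus_id = rownames(tpm), chrom = "chr1",
                      start = seq_len(nrow(tpm)) * 20000L,
                      end = seq_len(nrow(tpm)) * 20000L + 9471L,
                      strand = "+", class = "provirus",
                      ltr_subtype = "LTR5HS", esa_group = "Gorilla",
                      type = 2L, length = 9472L,
                      stringsAsFactors = FALSE)
  structure(list(counts = tpm, tpm = tpm,
                 lengths = ann$length, annotation = ann,
                 metadata = metadata, tpm_universe = "all"),
            class = "expression_matrix")
}

test_that("pattern classification follows the three published patterns", {
  n_tis <- 54L
  tissues <- sprintf("t%02d", seq_len(n_tis))
  types <- stats::setNames(rep(c("brain", "other"), c(10, 44)), tissues)
  e <- matrix(FALSE, 4, n_tis,
              dimnames = list(c("ubi", "brainy", "mix", "off"), tissues))
  e["ubi", 1:53] <- TRUE                 # 53/54 tissues
  e["brainy", 1:3] <- TRUE               # brain-type only
  e["mix", c(1, 54)] <- TRUE             # brain + other
  pat <- pattern_classify(e, types)
  expect_equal(unname(pat["ubi"]), "ubiquitous")
  expect_equal(unname(pat["brainy"]), "type_restricted")
  expect_equal(unname(pat["mix"]), "mixed")
  expect_equal(unname(pat["off"]), "silent")
  # deterministic and invariant to tissue order
  perm <- sample(n_tis)
  expect_equal(pat, pattern_classify(e[, perm], types))
})

test_that("ESA shares are group-size normalised and sum to 100", {
  # two groups, sizes 5 and 1, equal total expression -> shares 1:5
  loci <- sprintf("g%d", 1:6)
  ann <- data.frame(locus_id = loci, chrom = "chr1",
                    start = seq_len(6) * 20000L,
                    end = seq_len(6) * 20000L + 9471L, strand = "+",
                    class = "provirus", ltr_subtype = "LTR5HS",
                    esa_group = c(rep("Gorilla", 5), "Chimpanzee"),
                    type = 2L, length = 9472L, stringsAsFactors = FALSE)
  tpm <- matrix(c(rep(2, 5), 10), 6, 2,
                dimnames = list(loci, c("s1", "s2")))
  md <- data.frame(sample = c("s1", "s2"), tissue = "t1")
  em <- make_em(tpm, md, ann)
  esa <- esa_breakdown(em)
  b <- esa$breakdown
  expect_equal(sum(b$share_pct), 100, tolerance = 1e-9)
  gor <- b$share_pct[b$esa_group == "Gorilla"]
  chi <- b$share_pct[b$esa_group == "Chimpanzee"]
  expect_equal(chi / gor, 5, tolerance = 1e-9)
  # single nonzero group -> share 100
  tpm2 <- tpm; tpm2[6, ] <- 0
  esa2 <- esa_breakdown(make_em(tpm2, md, ann))
  expect_equal(esa2$breakdown$share_pct[esa2$breakdown$esa_group == "Gorilla"],
               100)
  # all-zero tissue -> NA shares
  esa3 <- esa_breakdown(make_em(tpm * 0, md, ann))
  expect_true(all(is.na(esa3$breakdown$share_pct)))
})

test_that("identical covariate groups give p near 1; shifted groups are flagged", {
  loci <- c("pvA", "pvB")
  samples <- sprintf("s%02d", 1:20)
  md <- data.frame(sample = samples, donor = samples, tissue = "t1",
                   sex = rep(c("M", "F"), each = 10),
                   age = 40L, age_group = "35-51", hardy = 2L)
  base <- seq(1, 4, length.out = 10)
  tpm <- rbind(pvA = c(base, base),                 # identical by sex
               pvB = c(base, base * 8))             # strong shift
  colnames(tpm) <- samples
  res <- covariate_tests(make_em(tpm, md), "sex")
  pa <- res$tests$p[res$tests$locus_id == "pvA"]
  expect_gt(pa, 0.999)
  expect_true(res$tests$significant[res$tests$locus_id == "pvB"])
})

test_that("Welch test keeps its nominal size and power on planted shifts", {
  # quick calibration (the full-depth run lives in the acceptance
  # suite): null rejection rate near alpha, near-certain detection of
  # a 2-sd shift at n = 50/50
  set.seed(2024)
  nulls <- replicate(400, stats::t.test(rnorm(25), rnorm(25))$p.value)
  rate <- mean(nulls < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
  hits <- replicate(100, stats::t.test(rnorm(50), rnorm(50, 2))$p.value < 0.05)
  expect_gt(mean(hits), 0.95)
})

test_that("hardy (4 groups) goes through ANOVA with Tukey pairs", {
  samples <- sprintf("s%02d", 1:24)
  md <- data.frame(sample = samples, donor = samples, tissue = "t1",
                   sex = "F", age = 40L, age_group = "35-51",
                   hardy = rep(1:4, each = 6))
  set.seed(5)
  tpm <- rbind(pvA = rnorm(24, 10) + 5 * (md$hardy == 4))
  colnames(tpm) <- samples
  res <- covariate_tests(make_em(tpm, md), "hardy")
  expect_true(res$tests$significant[1])
  expect_false(is.null(res$tukey))
  expect_equal(sort(unique(res$tukey$comparison)),
               c("2-1", "3-1", "3-2", "4-1", "4-2", "4-3"))
})

test_that("zero-variance expression returns NA with a warning, not an error", {
  samples <- sprintf("s%02d", 1:8)
  md <- data.frame(sample = samples, donor = samples, tissue = "t1",
                   sex = rep(c("M", "F"), each = 4), age = 40L,
                   age_group = "35-51", hardy = 2L)
  tpm <- rbind(pvA = rep(3, 8))
  colnames(tpm) <- samples
  expect_warning(res <- covariate_tests(make_em(tpm, md), "sex"),
                 "zero within-group variance")
  expect_true(is.na(res$tests$p[1]))
})

test_that("per-tissue totals equal per-sample sums", {
  g <- tiny_genome(2L, seed = 61)
  ds <- lapply(1:4, function(i)
    sample_design(sprintf("s%d", i), sprintf("d%d", i),
                  if (i <= 2) "brain" else "testis",
                  expression = c(pv01 = 1, pv02 = 2),
                  library_size = 300L, seed = i))
  sims <- stats::setNames(lapply(ds, function(d)
    simulate_reads(g, d)$records), sprintf("s%d", 1:4))
  em <- quantify_cohort(sims, g$annotation, emit_metadata(ds))
  ts <- tissue_summary(em)
  for (tt in unique(ts$samples$tissue)) {
    expect_equal(ts$tissues$mean_total[ts$tissues$tissue == tt],
                 mean(ts$samples$total_tpm[ts$samples$tissue == tt]))
  }
})
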