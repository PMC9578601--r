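# PWM scanning, exact p-values, MEME I/O and motif-matrix clustering.

test_that("pwm constructor validates shape and row sums", {
  expect_error(pwm("x", matrix(0.25, 3, 3)), "4 columns")
  bad <- matrix(0.3, 2, 4)
  expect_error(pwm("x", bad), "sum to 1")
  ok <- pwm_from_word("w", "ACGT")
  expect_equal(rowSums(ok$mat), rep(1, 4), ignore_attr = TRUE)
})

test_that("single-letter motif tail probability equals the letter mass", {
  pw <- pwm_from_word("A1", "A", p = 0.97)
  d <- pwm_score_distribution(pw, bg = rep(0.25, 4))
  # the best score is attained only by A: p-value 0.25 under uniform bg
  expect_equal(min(d$pvalue), 0.25)
})

test_that("DP p-values equal brute-force enumeration (length-4 motif)", {
  bg <- c(0.3, 0.2, 0.3, 0.2)
  pw <- pwm_from_word("T1", "ACGT", p = 0.8)
  d <- pwm_score_distribution(pw, bg)
  S <- provex:::pwm_int_scores(pw, bg, 0.01, 1e-3)
  words <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  sc <- S[1, words[, 1]] + S[2, words[, 2]] + S[3, words[, 3]] +
    S[4, words[, 4]]
  pr <- bg[words[, 1]] * bg[words[, 2]] * bg[words[, 3]] * bg[words[, 4]]
  for (s in unique(sc)) {
    expect_equal(d$pvalue[match(s, d$scores_int)], sum(pr[sc >= s]),
                 tolerance = 1e-9)
  }
})

test_that("palindromic motifs match identically on both strands", {
  pw <- pwm_from_word("P", "ACGT")  # reverse complement of ACGT is ACGT
  seqx <- paste0("CCCCC", "ACGT", "CCCCC", "ACGT", "CC")
  hits <- pwm_scan(seqx, pw, p_threshold = 0.01, bg = rep(0.25, 4))
  fw <- hits[hits$strand == "+", ]
  rv <- hits[hits$strand == "-", ]
  expect_equal(fw$pos, rv$pos)
  expect_equal(fw$score, rv$score)
})

test_that("motif longer than the sequence yields an empty match list", {
  pw <- pwm_from_word("L", "ACGTACGTAC")
  expect_equal(nrow(pwm_scan("ACGT", pw)), 0L)
})

test_that("bundled MEME file round-trips and matches the in-code motifs", {
  path <- system.file("extdata", "motifs", "hml2_toy.meme",
                      package = "provex")
  expect_true(nzchar(path))
  m <- read_meme(path)
  ref <- hml2_toy_motifs()
  expect_setequal(names(m), names(ref))
  for (id in names(ref))
    expect_equal(m[[id]]$mat, ref[[id]]$mat, tolerance = 1e-5)
  # write -> read is stable
  tmp <- tempfile(fileext = ".meme")
  write_meme(m, tmp)
  m2 <- read_meme(tmp)
  expect_equal(m2$HS1$mat, m$HS1$mat, tolerance = 1e-9)
  expect_error(suppressWarnings(read_meme(tempfile())),
               "cannot open|No such")
})

test_that("planted subtype words are detected at p <= 1e-4, with one mismatch", {
  pw <- pwm_from_word("HS1", "GGACGTCAGC")
  bgu <- rep(0.25, 4)
  hit0 <- pwm_scan(paste0(strrep("CA", 30), "GGACGTCAGC", strrep("CT", 30)),
                   pw, bg = bgu)
  expect_equal(nrow(hit0), 1L)
  expect_equal(hit0$pos, 61L)
  # one substitution still matches at the 1e-4 threshold
  hit1 <- pwm_scan(paste0(strrep("CA", 30), "GGACGTAAGC", strrep("CT", 30)),
                   pw, bg = bgu)
  expect_equal(nrow(hit1), 1L)
  # two substitutions do not
  hit2 <- pwm_scan(paste0(strrep("CA", 30), "GGACGTAAGA", strrep("CT", 30)),
                   pw, bg = bgu)
  expect_equal(nrow(hit2), 0L)
})

test_that("disjoint motif sets split into two fully supported clades", {
  m <- rbind(
    l1 = c(1, 1, 1, 0, 0, 0), l2 = c(1, 1, 1, 0, 0, 0),
    l3 = c(1, 1, 1, 0, 0, 0),
    r1 = c(0, 0, 0, 1, 1, 1), r2 = c(0, 0, 0, 1, 1, 1),
    r3 = c(0, 0, 0, 1, 1, 1))
  colnames(m) <- sprintf("m%d", 1:6)
  cl <- motif_cluster(m, bootstrap = 200, seed = 1)
  left <- cl$clades[cl$clades$members == "l1,l2,l3", ]
  right <- cl$clades[cl$clades$members == "r1,r2,r3", ]
  expect_equal(left$support, 1)
  expect_equal(right$support, 1)
})

test_that("an LTR with unique motifs is separated with them as defining", {
  set.seed(8)
  base <- matrix(rbinom(5 * 10, 1, 0.5), 5, 10,
                 dimnames = list(sprintf("ltr%d", 1:5), sprintf("m%02d", 1:10)))
  uniq <- matrix(0L, 6, 48, dimnames = list(NULL, sprintf("u%02d", 1:48)))
  uniq[6, ] <- 1L
  m <- cbind(rbind(base, special = base[1, ] * 0L), uniq)
  rownames(m)[6] <- "special"
  cl <- motif_cluster(m, bootstrap = 100, seed = 2)
  own <- cl$defining[cl$defining$members == "special", ]
  expect_equal(nrow(own), 1L)
  expect_equal(own$n_defining, 48L)
})

test_that("clustering is invariant to LTR input order", {
  set.seed(9)
  m <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12,
              dimnames = list(sprintf("L%d", 1:8), sprintf("m%02d", 1:12)))
  m[1, ] <- 1L  # guarantee variation
  c1 <- motif_cluster(m, bootstrap = 0)
  c2 <- motif_cluster(m[sample(8), ], bootstrap = 0)
  expect_identical(c1$clades$members, c2$clades$members)
})

test_that("a constant matrix is rejected", {
  m <- matrix(1L, 4, 3, dimnames = list(letters[1:4], c("x", "y", "z")))
  expect_error(motif_cluster(m), "no variation")
})

test_that("simulated LTRs cluster by subtype in sequence and motif space", {
  specs <- list(
    provirus_spec("hs1", "chr1", 6000L, ltr_subtype = "LTR5HS"),
    provirus_spec("hs2", "chr1", 26000L, ltr_subtype = "LTR5HS"),
    provirus_spec("a1", "chr1", 46000L, ltr_subtype = "LTR5A"),
    provirus_spec("a2", "chr1", 66000L, ltr_subtype = "LTR5A"),
    provirus_spec("b1", "chr1", 86000L, ltr_subtype = "LTR5B"),
    provirus_spec("b2", "chr1", 106000L, ltr_subtype = "LTR5B"))
  g <- build_genome(specs, seed = 21)
  ltrs <- extract_ltrs(g)
  # sequence space: within-subtype p-distances below cross-subtype
  msa <- ltr_msa(ltrs)
  D <- p_distance(msa)
  sub <- ltrs$subtype[match(rownames(D), ltrs$ltr_id)]
  same <- D[outer(sub, sub, "==") & upper.tri(D)]
  diff <- D[outer(sub, sub, "!=") & upper.tri(D)]
  expect_lt(max(same), min(diff))
  # motif space: the three subtype member sets appear as clades
  pres <- motif_presence(ltrs, hml2_toy_motifs())
  cl <- motif_cluster(pres, bootstrap = 100, seed = 3)
  for (st in c("LTR5HS", "LTR5A", "LTR5B")) {
    want <- paste(sort(ltrs$ltr_id[ltrs$subtype == st]), collapse = ",")
    expect_true(want %in% cl$clades$members, label = paste("clade", st))
  }
})
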