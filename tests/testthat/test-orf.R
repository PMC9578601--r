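# Alignment, coordinate projection and ORF lesion scanning.

tpl <- hml2_template()

test_that("identical sequences align gaplessly at 100% identity", {
  aln <- align_to_reference(tpl$sequence, tpl$sequence)
  expect_equal(aln$identity, 1)
  expect_false(grepl("-", aln$provirus, fixed = TRUE))
  expect_false(grepl("-", aln$reference, fixed = TRUE))
})

test_that("alignment scores match an independent implementation", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(17)
  for (i in 1:6) {
    n <- sample(80:300, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    bc <- strsplit(a, "")[[1]]
    bc[sample(n, 8)] <- sample(c("A", "C", "G", "T"), 8, TRUE)
    if (i %% 2 == 0) bc <- bc[-(20:24)]
    if (i %% 3 == 0) bc <- append(bc, c("G", "G"), after = 40)
    b <- paste(bc, collapse = "")
    ours <- align_to_reference(b, a)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(b), Biostrings::DNAString(a), type = "global",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    expect_equal(ours, Biostrings::score(ref), tolerance = 1e-9)
  }
})

test_that("a planted 292-nt deletion appears as a single gap run", {
  mut <- apply_lesions(tpl$sequence, list(lesion("deletion", 6690, 292)))
  aln <- align_to_reference(mut$sequence, tpl$sequence)
  runs <- rle(strsplit(aln$provirus, "")[[1]] == "-")
  gaps <- runs$lengths[runs$values]
  expect_equal(gaps, 292L)
})

test_that("empty or non-DNA input is rejected with positions", {
  expect_error(align_to_reference("", tpl$sequence), "empty")
  expect_error(align_to_reference("ACGTNNACGT", tpl$sequence),
               "position.*5")
})

test_that("projection recovers reference interval lengths", {
  aln <- align_to_reference(tpl$sequence, tpl$sequence)
  segs <- project_segments(aln)
  expect_equal(nchar(segs$gag$sequence), 2001L)  # 3112 - 1112 + 1
  expect_equal(nchar(segs$pro$sequence), 981L)
  expect_equal(nchar(segs$pol$sequence), 2835L)
  expect_equal(nchar(segs$env$sequence), 2100L)
  expect_equal(nchar(segs$rec$sequence), 261L + 57L)   # spliced parts
  expect_equal(nchar(segs$np9$sequence), 44L + 181L)
  # round trip: identical sequence means no events anywhere
  expect_true(all(vapply(segs, function(s) nrow(s$events) == 0L, TRUE)))
})

test_that("a type 1 provirus carries the 292-nt deletion in env", {
  mut <- apply_lesions(tpl$sequence, list(lesion("deletion", 6690, 292)))
  aln <- align_to_reference(mut$sequence, tpl$sequence)
  segs <- project_segments(aln)
  ev <- segs$env$events
  expect_true(any(ev$type == "deletion" & ev$length == 292L))
  expect_false(scan_orf(segs$env)$intact)
  expect_false(scan_orf(segs$rec)$intact)
  expect_true(scan_orf(segs$np9)$intact)
})

test_that("scan_orf detects each lesion kind (direct-translation oracle)", {
  # lesion-free template: all genes intact
  segs0 <- project_segments(align_to_reference(tpl$sequence, tpl$sequence))
  expect_true(all(vapply(segs0, function(s) scan_orf(s)$intact, TRUE)))

  # nonsense substitution at gag codon 5: TAA planted at the exact
  # template coordinates; oracle = direct translation of the interval
  gag_start <- 1112L
  pos <- gag_start + 12L
  mut <- apply_lesions(tpl$sequence,
                       list(lesion("substitution", pos, "TAA")))
  aa <- oracle_translate_interval(mut$sequence, 1112L, 3112L)
  expect_equal(which(aa == "*")[1], 5L)
  segs <- project_segments(align_to_reference(mut$sequence, tpl$sequence))
  v <- scan_orf(segs$gag)
  expect_false(v$intact)
  expect_equal(v$premature_stop_codon, 5L)

  # single-base insertion at gag nt 10 -> frameshift
  mut2 <- apply_lesions(tpl$sequence,
                        list(lesion("insertion", gag_start + 9L, "G")))
  segs2 <- project_segments(align_to_reference(mut2$sequence, tpl$sequence))
  v2 <- scan_orf(segs2$gag)
  expect_false(v2$intact)
  expect_true(any(grepl("frameshifting insertion of 1", v2$lesions)))

  # 4-bp duplication -> frameshift (4 %% 3 != 0)
  mut3 <- apply_lesions(tpl$sequence,
                        list(lesion("duplication", gag_start + 30L, 4L)))
  segs3 <- project_segments(align_to_reference(mut3$sequence, tpl$sequence))
  expect_false(scan_orf(segs3$gag)$intact)

  # small in-frame deletion (9 nt, < 5% of gag): lesion reported but
  # intactness kept
  mut4 <- apply_lesions(tpl$sequence,
                        list(lesion("deletion", gag_start + 300L, 9L)))
  segs4 <- project_segments(align_to_reference(mut4$sequence, tpl$sequence))
  v4 <- scan_orf(segs4$gag)
  expect_true(v4$intact)

  # large in-frame deletion (> 5%) breaks intactness
  mut5 <- apply_lesions(tpl$sequence,
                        list(lesion("deletion", gag_start + 300L, 150L)))
  segs5 <- project_segments(align_to_reference(mut5$sequence, tpl$sequence))
  expect_false(scan_orf(segs5$gag)$intact)
})

test_that("segment shorter than a codon or fully deleted reports absent", {
  genes <- data.frame(gene = "gag", part = 1L, start = 1112L, end = 3112L)
  mut <- apply_lesions(tpl$sequence, list(lesion("deletion", 1100L, 2050L)))
  segs <- project_segments(align_to_reference(mut$sequence, tpl$sequence),
                           genes)
  v <- scan_orf(segs$gag)
  expect_true(v$absent)
  expect_false(v$intact)
})

test_that("GagProPol context rules and type handling", {
  mk_verdict <- function(gene, intact)
    structure(list(gene = gene, intact = intact, absent = FALSE,
                   lesions = if (intact) character(0) else "premature stop at codon 2",
                   premature_stop_codon = NA_integer_),
              class = "orf_verdict")
  verd <- lapply(stats::setNames(nm = c("gag", "pro", "pol", "env",
                                        "rec", "np9")),
                 function(g) mk_verdict(g, TRUE))
  # all clean, type 2: np9 not applicable
  r2 <- classify_provirus(verd, provirus_type = 2L)
  expect_true(all(r2$intact[r2$gene %in% c("gag", "pro", "pol", "env", "rec")]))
  expect_false(r2$intact[r2$gene == "np9"])
  # all clean, type 1: np9 intact, env/rec non-expressible
  r1 <- classify_provirus(verd, provirus_type = 1L)
  expect_true(r1$intact[r1$gene == "np9"])
  expect_false(any(r1$intact[r1$gene %in% c("env", "rec")]))
  # gag disrupted but pro ORF clean: pro loses context
  verd$gag <- mk_verdict("gag", FALSE)
  rg <- classify_provirus(verd, provirus_type = 2L)
  expect_true(rg$orf_intact[rg$gene == "pro"])
  expect_false(rg$context_ok[rg$gene == "pro"])
  expect_false(rg$intact[rg$gene == "pro"])
  expect_false(rg$intact[rg$gene == "pol"])
})

test_that("adding a lesion never turns a non-intact gene intact (monotone)", {
  set.seed(41)
  gag <- c(1112L, 3112L)
  for (rep_i in 1:5) {
    codon <- sample(2:600, 1)
    l1 <- lesion("substitution", gag[1] + 3L * (codon - 1L), "TAA")
    l2 <- lesion("insertion", sample(gag[1]:(gag[2] - 3L), 1), "C")
    s1 <- apply_lesions(tpl$sequence, list(l1))
    s12 <- apply_lesions(tpl$sequence, list(l1, l2))
    g1 <- scan_orf(project_segments(
      align_to_reference(s1$sequence, tpl$sequence))$gag)
    g12 <- scan_orf(project_segments(
      align_to_reference(s12$sequence, tpl$sequence))$gag)
    expect_false(g1$intact)
    expect_false(g12$intact)
  }
})
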