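# Probabilistic reassignment of multimapping reads to proviral loci.
#
# Model: each read i carries candidate locations j with weights q_ij
# derived from alignment scores (softmax); locus proportions pi_j are
# mixture weights. EM alternates responsibilities
# r_ij = pi_j q_ij / sum_k pi_k q_ik with the update
# pi_j = (sum_i r_ij + prior) / (n + K * prior), maximising the
# observed-data log-likelihood sum_i log sum_j pi_j q_ij. Fractional
# counts are sum_i r_ij at convergence.

#' Load candidate alignments per read from SAM
#'
#' Groups SAM records by read name, assigns each record to the
#' annotated locus it overlaps (priority provirus > solo LTR > host
#' gene, then largest overlap), and pools records overlapping no locus
#' into a `"background"` category. Alignment scores (`AS`) are kept;
#' multiple records of one read on the same locus collapse to the best
#' score.
#'
#' @param sam Path to a SAM file, or the `records` data.frame of
#'   [read_sam()]/[simulate_reads()].
#' @param annotation Annotation table (from [build_genome()] or
#'   [read_annotation()]).
#' @param sample_id Optional sample label.
#' @return An object of class `alignment_set`: list with `candidates`
#'   (data.frame `read`, `locus`, `score`), `loci` (quantifiable locus
#'   ids), `n_reads`, `sample_id`.
#' @export
load_alignments <- function(sam, annotation, sample_id = NA_character_) {
  records <- if (is.character(sam)) read_sam(sam)$records else sam
  feats <- annotation[annotation$class %in%
                        c("provirus", "solo_LTR", "host_gene"), , drop = FALSE]
  loci <- sort(feats$locus_id)
  if (nrow(records) == 0L) {
    return(structure(list(
      candidates = data.frame(read = character(), locus = character(),
                              score = numeric()),
      loci = loci, n_reads = 0L, sample_id = sample_id),
      class = "alignment_set"))
  }
  rl <- nchar(records$seq)
  # locus assignment by interval overlap (per chromosome)
  assigned <- rep("background", nrow(records))
  prio <- c(provirus = 1L, solo_LTR = 2L, host_gene = 3L)
  for (ch in unique(records$rname)) {
    f <- feats[feats$chrom == ch, , drop = FALSE]
    if (!nrow(f)) next
    sel <- which(records$rname == ch)
    q <- IRanges::IRanges(start = records$pos[sel],
                          end = records$pos[sel] + rl[sel] - 1L)
    s <- IRanges::IRanges(start = f$start, end = f$end)
    hits <- IRanges::findOverlaps(q, s)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ow <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
    o <- order(qh, prio[f$class[sh]], -ow)
    first <- !duplicated(qh[o])
    assigned[sel[qh[o][first]]] <- f$locus_id[sh[o][first]]
  }
  cand <- data.frame(read = records$qname, locus = assigned,
                     score = as.numeric(records$as),
                     stringsAsFactors = FALSE)
  # best score per (read, locus)
  o <- order(cand$read, cand$locus, -cand$score)
  cand <- cand[o, , drop = FALSE]
  cand <- cand[!duplicated(cand[c("read", "locus")]), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, loci = loci,
                 n_reads = length(unique(cand$read)),
                 sample_id = sample_id),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  multi <- sum(table(x$candidates$read) > 1L)
  cat("alignment_set:", x$n_reads, "reads (", multi, "multimapping ),",
      length(x$loci), "quantifiable loci\n")
  invisible(x)
}

#' Reassign multimapping reads by EM
#'
#' @param aln An [load_alignments()] result (or a compatible list with
#'   a `candidates` data.frame).
#' @param prior_weight Dirichlet-style pseudo-count added to every
#'   locus in the M step; 0 gives maximum likelihood.
#' @param tol Convergence tolerance on `max |delta pi|`.
#' @param max_iter Iteration cap.
#' @param temperature Softmax temperature converting alignment scores
#'   to initial candidate weights `q_ij` (larger = flatter).
#' @return An object of class `mixture_state`: list with `pi`
#'   (named locus proportions), `counts` (fractional read counts,
#'   summing to the number of reads), `responsibilities`,
#'   `log_likelihood` (trace, non-decreasing), `iterations`,
#'   `converged`.
#' @export
reassign_em <- function(aln, prior_weight = 0, tol = 1e-6,
                        max_iter = 1000L, temperature = 1) {
  stopifnot(tol > 0, prior_weight >= 0)
  cand <- aln$candidates
  if (nrow(cand) == 0L) {
    counts <- stats::setNames(numeric(length(aln$loci)), aln$loci)
    return(structure(list(pi = counts, counts = counts,
                          responsibilities = cand,
                          log_likelihood = numeric(0), iterations = 0L,
                          converged = TRUE, n_reads = 0L),
                     class = "mixture_state"))
  }
  if (any(!is.finite(cand$score))) {
    bad <- cand$read[!is.finite(cand$score)][1]
    stop("non-finite alignment score for read ", bad)
  }
  read_f <- factor(cand$read)
  locus_f <- factor(cand$locus, levels = sort(unique(cand$locus)))
  ri <- as.integer(read_f); li <- as.integer(locus_f)
  n <- nlevels(read_f); K <- nlevels(locus_f)

  # softmax of scores within read
  smax <- tapply(cand$score, ri, max)[as.character(ri)]
  q <- exp((cand$score - as.numeric(smax)) / temperature)
  qz <- tapply(q, ri, sum)
  if (any(qz == 0)) {
    bad <- levels(read_f)[which(qz == 0)[1]]
    stop("read ", bad, " has all-zero candidate weights")
  }

  pi <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    w <- pi[li] * q
    denom <- as.vector(rowsum(w, ri, reorder = TRUE))
    ll_trace <- c(ll_trace, sum(log(denom)) - sum(log(as.numeric(qz))))
    r <- w / denom[ri]
    counts <- as.vector(rowsum(r, li, reorder = TRUE))
    # loci with no candidate rows keep count 0
    full_counts <- numeric(K)
    full_counts[sort(unique(li))] <- counts
    pi_new <- (full_counts + prior_weight) / (n + K * prior_weight)
    delta <- max(abs(pi_new - pi))
    pi <- pi_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  names(pi) <- levels(locus_f)
  counts <- stats::setNames(numeric(K), levels(locus_f))
  w <- pi[li] * q
  denom <- as.vector(rowsum(w, ri, reorder = TRUE))
  r <- w / denom[ri]
  cfin <- as.vector(rowsum(r, li, reorder = TRUE))
  counts[sort(unique(li))] <- cfin

  structure(list(pi = pi / sum(pi), counts = counts,
                 responsibilities = data.frame(read = cand$read,
                                               locus = cand$locus,
                                               r = r),
                 log_likelihood = ll_trace, iterations = it,
                 converged = converged, n_reads = n),
            class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat("mixture_state:", x$n_reads, "reads,", length(x$pi), "categories,",
      x$iterations, "EM iterations",
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Convert counts to TPM
#'
#' `rate_j = count_j / length_j`; `TPM_j = 1e6 * rate_j / sum(rate)`,
#' per sample (column). TPM therefore normalises for both feature
#' length and library size; each column sums to 1e6.
#'
#' @param counts Numeric matrix (features x samples) or vector.
#' @param lengths Feature lengths (nt), recycled across columns.
#' @return TPM matrix of the same shape.
#' @export
counts_to_tpm <- function(counts, lengths) {
  vec <- is.null(dim(counts))
  m <- as.matrix(counts)
  if (length(lengths) != nrow(m))
    stop("lengths must have one entry per feature")
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  rate <- m / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s); TPM column(s) set to 0")
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  if (vec) tpm[, 1L] else tpm
}

#' Call expressed loci per tissue
#'
#' A locus is called expressed in a tissue when its mean TPM across
#' that tissue's samples is at or above the threshold (default 1 TPM).
#'
#' @param tpm TPM matrix (loci x samples).
#' @param metadata Metadata data.frame with columns `sample`, `tissue`
#'   ([emit_metadata()] layout).
#' @param threshold Expression threshold in TPM (>= 0).
#' @return A list with `expressed` (logical loci x tissues matrix),
#'   `mean_tpm` (matching numeric matrix) and `per_tissue_counts`.
#' @export
call_expressed <- function(tpm, metadata, threshold = 1) {
  stopifnot(threshold >= 0)
  md <- metadata[match(colnames(tpm), metadata$sample), ]
  if (anyNA(md$tissue)) stop("samples missing from metadata: ",
                             colnames(tpm)[is.na(md$tissue)][1])
  tissues <- unique(md$tissue)
  empty <- tissues[!tissues %in% md$tissue]
  if (length(empty)) {
    warning("tissue(s) without samples excluded: ",
            paste(empty, collapse = ", "))
    tissues <- setdiff(tissues, empty)
  }
  mean_tpm <- vapply(tissues, function(tt)
    rowMeans(tpm[, md$tissue == tt, drop = FALSE]),
    numeric(nrow(tpm)))
  if (is.null(dim(mean_tpm)))
    mean_tpm <- matrix(mean_tpm, nrow = nrow(tpm),
                       dimnames = list(rownames(tpm), tissues))
  expressed <- mean_tpm >= threshold
  list(expressed = expressed, mean_tpm = mean_tpm,
       per_tissue_counts = colSums(expressed))
}

#' Quantify one sample from SAM to fractional counts
#'
#' @inheritParams load_alignments
#' @inheritParams reassign_em
#' @return Named fractional counts over all annotated loci (background
#'   category dropped), attributes `state` and `n_reads`.
#' @export
quantify_sample <- function(sam, annotation, sample_id = NA_character_,
                            prior_weight = 0, tol = 1e-6,
                            max_iter = 1000L, temperature = 1) {
  aln <- load_alignments(sam, annotation, sample_id)
  st <- reassign_em(aln, prior_weight = prior_weight, tol = tol,
                    max_iter = max_iter, temperature = temperature)
  counts <- stats::setNames(numeric(length(aln$loci)), aln$loci)
  got <- intersect(names(st$counts), aln$loci)
  counts[got] <- st$counts[got]
  attr(counts, "state") <- st
  attr(counts, "n_reads") <- aln$n_reads
  counts
}

#' Quantify a cohort of samples into an expression matrix
#'
#' Runs [quantify_sample()] per SAM file and assembles fractional
#' counts and TPM with the sample metadata attached.
#'
#' @param sams Named list/vector: sample_id -> SAM path or records
#'   data.frame.
#' @param annotation Locus annotation table.
#' @param metadata Sample metadata ([emit_metadata()] layout).
#' @param tpm_universe `"all"`: TPM denominators run over all annotated
#'   features; `"hml2"`: over proviral loci only.
#' @inheritParams reassign_em
#' @return An object of class `expression_matrix`: list with `counts`,
#'   `tpm` (features x samples), `lengths`, `annotation`, `metadata`.
#' @export
quantify_cohort <- function(sams, annotation, metadata,
                            tpm_universe = c("all", "hml2"),
                            prior_weight = 0, tol = 1e-6,
                            max_iter = 1000L, temperature = 1) {
  tpm_universe <- match.arg(tpm_universe)
  ids <- names(sams)
  if (is.null(ids)) stop("sams must be named by sample_id")
  counts <- vapply(ids, function(sid)
    quantify_sample(sams[[sid]], annotation, sid,
                    prior_weight = prior_weight, tol = tol,
                    max_iter = max_iter, temperature = temperature),
    numeric(length(sort(annotation$locus_id[annotation$class %in%
      c("provirus", "solo_LTR", "host_gene")]))))
  lengths <- annotation$length[match(rownames(counts), annotation$locus_id)]
  universe <- if (tpm_universe == "all") rep(TRUE, nrow(counts))
              else annotation$class[match(rownames(counts),
                                          annotation$locus_id)] == "provirus"
  tpm <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  tpm[universe, ] <- counts_to_tpm(counts[universe, , drop = FALSE],
                                   lengths[universe])
  structure(list(counts = counts, tpm = tpm, lengths = lengths,
                 annotation = annotation, metadata = metadata,
                 tpm_universe = tpm_universe),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "features x",
      ncol(x$counts), "samples (TPM universe:", x$tpm_universe, ")\n")
  invisible(x)
}
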