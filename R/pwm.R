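# Position weight matrix scanning with exact p-values.
#
# Log-odds scores (PWM vs a 0-order background, pseudocount added) are
# discretised to a fine bit grid; the null distribution of the
# discretised score under the background model is computed exactly by
# dynamic programming (convolution over motif columns), giving an
# exact p-value for every attainable score. Matches are positions, on
# either strand, whose score p-value is at or below the threshold.

#' Construct a position weight matrix object
#'
#' @param id Motif identifier.
#' @param mat Numeric matrix, one row per motif position, columns
#'   `A`, `C`, `G`, `T`, rows summing to 1.
#' @param name Transcription factor name (defaults to `id`).
#' @param nsites Number of sites the motif was built from.
#' @return An object of class `pwm`.
#' @export
pwm <- function(id, mat, name = id, nsites = 20L) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(mat) <- DNA_BASES
  if (any(mat < 0)) stop("PWM probabilities must be >= 0")
  if (max(abs(rowSums(mat) - 1)) > 1e-6)
    stop("PWM rows must sum to 1")
  structure(list(id = id, name = name, mat = mat,
                 nsites = as.integer(nsites)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "(", x$name, "):", nrow(x$mat), "positions, consensus",
    paste(DNA_BASES[apply(x$mat, 1L, which.max)], collapse = ""), "\n")
  invisible(x)
}

#' Build a PWM from a consensus word
#'
#' The consensus base gets probability `p`, the three others share the
#' remainder equally.
#'
#' @param id Motif id.
#' @param word Consensus DNA word.
#' @param p Consensus base probability.
#' @inheritParams pwm
#' @return A [pwm()].
#' @export
pwm_from_word <- function(id, word, p = 0.85, name = id, nsites = 20L) {
  chars <- strsplit(toupper(word), "")[[1]]
  mat <- matrix((1 - p) / 3, length(chars), 4L,
                dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(chars)) mat[i, chars[i]] <- p
  pwm(id, mat, name = name, nsites = nsites)
}

#' The bundled toy motif set
#'
#' Eleven short motifs matching the transcription-factor binding words
#' the genome builder plants in LTR U3 regions: three specific to each
#' LTR subtype (sharing position slots) and two common to all
#' subtypes. Shipped also as a MEME minimal-format file under
#' `inst/extdata/motifs/`.
#'
#' @return Named list of [pwm()] objects.
#' @export
hml2_toy_motifs <- function() {
  ms <- .motif_sites()
  out <- lapply(seq_len(nrow(ms)), function(i)
    pwm_from_word(ms$motif[i], ms$word[i]))
  stats::setNames(out, ms$motif)
}

# integer-discretised log-odds score matrix (bits / bin)
pwm_int_scores <- function(pwm, bg, pseudocount = 0.01, bin = 1e-3) {
  p <- sweep(pwm$mat + pseudocount * matrix(bg, nrow(pwm$mat), 4L,
                                            byrow = TRUE),
             1L, 1 + pseudocount, "/")
  lo <- log2(sweep(p, 2L, bg, "/"))
  round(lo / bin)
}

#' Exact null distribution of a discretised PWM score
#'
#' @param pwm A [pwm()].
#' @param bg Background letter frequencies (A, C, G, T), summing to 1.
#' @param pseudocount Pseudocount fraction added to the PWM.
#' @param bin Score discretisation width in bits.
#' @return A list with `scores` (attainable integer scores * bin, in
#'   bits), `prob`, and `pvalue` (upper-tail probability at each
#'   score).
#' @export
pwm_score_distribution <- function(pwm, bg = rep(0.25, 4),
                                   pseudocount = 0.01, bin = 1e-3) {
  if (abs(sum(bg) - 1) > 1e-6) stop("background must sum to 1")
  S <- pwm_int_scores(pwm, bg, pseudocount, bin)
  # DP convolution: start with the point mass at 0
  cur <- 1
  cur_off <- 0L                      # cur[k] = P(sum == cur_off + k - 1)
  for (r in seq_len(nrow(S))) {
    new_off <- cur_off + min(S[r, ])
    new_len <- (cur_off + max(S[r, ])) - new_off + length(cur)
    nxt <- numeric(new_len)
    for (b in 1:4) {
      sh <- cur_off + S[r, b] - new_off
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt; cur_off <- new_off
  }
  scores_int <- cur_off + seq_along(cur) - 1L
  pv <- rev(cumsum(rev(cur)))
  list(scores = scores_int * bin, scores_int = scores_int,
       prob = cur, pvalue = pv, bin = bin)
}

# smallest integer score whose p-value is <= threshold (NA if none)
pwm_score_threshold <- function(dist, p_threshold) {
  ok <- dist$pvalue <= p_threshold
  if (!any(ok)) return(NA_integer_)
  dist$scores_int[which(ok)[1]]
}

#' Scan a sequence with a PWM
#'
#' Scores every position on both strands and reports matches whose
#' exact p-value under the background model is at or below the
#' threshold.
#'
#' @param sequence DNA string (gaps and other non-ACGT characters are
#'   stripped before scanning).
#' @param pwm A [pwm()].
#' @param p_threshold Match p-value threshold (default 1e-4).
#' @param bg Background frequencies; default estimated from the
#'   scanned sequence (0-order), with a uniform fallback.
#' @param both_strands Scan the reverse complement too.
#' @param pseudocount,bin See [pwm_score_distribution()].
#' @return data.frame `motif`, `pos` (1-based, forward coordinates of
#'   the match start), `strand`, `score` (bits), `pvalue`.
#' @export
pwm_scan <- function(sequence, pwm, p_threshold = 1e-4, bg = NULL,
                     both_strands = TRUE, pseudocount = 0.01, bin = 1e-3,
                     .dist = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  seq_clean <- gsub("[^ACGT]", "", toupper(sequence))
  L <- nrow(pwm$mat)
  empty <- data.frame(motif = character(), pos = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  if (nchar(seq_clean) < L) return(empty)
  if (is.null(bg)) bg <- estimate_background(seq_clean)
  dist <- .dist %||% pwm_score_distribution(pwm, bg, pseudocount, bin)
  thr <- pwm_score_threshold(dist, p_threshold)
  if (is.na(thr)) return(empty)
  S <- pwm_int_scores(pwm, bg, pseudocount, bin)
  pv_at <- function(s) dist$pvalue[match(s, dist$scores_int)]

  scan_one <- function(x) {
    code <- match(strsplit(x, "")[[1]], DNA_BASES)
    n <- length(code) - L + 1L
    if (n < 1L) return(NULL)
    sc <- integer(n)
    for (r in seq_len(L)) sc <- sc + S[r, ][code[seq_len(n) + r - 1L]]
    hit <- which(sc >= thr)
    if (!length(hit)) return(NULL)
    data.frame(pos = hit, score_int = sc[hit])
  }
  out <- list()
  fw <- scan_one(seq_clean)
  if (!is.null(fw))
    out[[1L]] <- data.frame(motif = pwm$id, pos = fw$pos, strand = "+",
                            score = fw$score_int * bin,
                            pvalue = pv_at(fw$score_int),
                            stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- scan_one(revcomp(seq_clean))
    if (!is.null(rc))
      out[[length(out) + 1L]] <- data.frame(
        motif = pwm$id,
        pos = nchar(seq_clean) - (rc$pos + L - 1L) + 1L, strand = "-",
        score = rc$score_int * bin, pvalue = pv_at(rc$score_int),
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$pos), , drop = FALSE]
}

#' Estimate 0-order background letter frequencies
#'
#' @param sequences Character vector of DNA strings.
#' @return Frequencies of A, C, G, T (pseudocount 1 each).
#' @export
estimate_background <- function(sequences) {
  chars <- strsplit(paste(toupper(sequences), collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = DNA_BASES)) + 1
  as.numeric(counts / sum(counts))
}

#' Binary motif-presence matrix over LTRs
#'
#' A motif is present in an LTR when it has at least one match at or
#' below the p-value threshold anywhere in the LTR (either strand).
#'
#' @param ltrs [extract_ltrs()] table or named character vector of LTR
#'   sequences.
#' @param pwms List of [pwm()] objects.
#' @param p_threshold Match threshold (default 1e-4).
#' @param bg Background; default estimated from the full LTR set.
#' @return Binary integer matrix, LTRs x motifs.
#' @export
motif_presence <- function(ltrs, pwms, p_threshold = 1e-4, bg = NULL) {
  seqs <- if (is.data.frame(ltrs))
    stats::setNames(ltrs$sequence, ltrs$ltr_id) else ltrs
  if (is.null(bg)) bg <- estimate_background(unlist(seqs))
  ids <- vapply(pwms, `[[`, "", "id")
  m <- matrix(0L, length(seqs), length(pwms),
              dimnames = list(names(seqs), ids))
  for (j in seq_along(pwms)) {
    dist <- pwm_score_distribution(pwms[[j]], bg)
    for (i in seq_along(seqs)) {
      hits <- pwm_scan(seqs[[i]], pwms[[j]], p_threshold = p_threshold,
                       bg = bg, .dist = dist)
      m[i, j] <- as.integer(nrow(hits) > 0L)
    }
  }
  m
}
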