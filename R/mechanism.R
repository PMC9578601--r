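# Mechanism classification: LTR-driven vs read-through transcription,
# operationalising read-coverage inspection. LTR-driven units show
# read starts clustered at the U3-R border of the driving LTR and no
# coverage upstream of it; read-through units show continuous coverage
# entering the provirus from upstream.

#' Read coverage and start profile around a locus
#'
#' Uses primary alignments only. Depth and read-start counts are
#' computed over the locus plus a flank on each side.
#'
#' @param sam SAM path or records data.frame.
#' @param annotation Locus annotation table.
#' @param locus_id Locus of interest.
#' @param flank Flank width in nt (default 2000).
#' @return An object of class `coverage_profile`: list with `locus`,
#'   `chrom`, `window_start`, `depth` (integer vector over the
#'   window), `starts` (read-start counts), `n_reads`.
#' @export
coverage_profile <- function(sam, annotation, locus_id, flank = 2000L) {
  i <- match(locus_id, annotation$locus_id)
  if (is.na(i)) stop("locus not in annotation: ", locus_id)
  records <- if (is.character(sam)) read_sam(sam)$records else sam
  win_s <- max(1L, annotation$start[i] - flank)
  win_e <- annotation$end[i] + flank
  wlen <- win_e - win_s + 1L
  depth <- integer(wlen); starts <- integer(wlen)
  if (nrow(records)) {
    prim <- bitwAnd(records$flag, SAM_FLAG_SECONDARY) == 0L &
      records$rname == annotation$chrom[i]
    r <- records[prim, , drop = FALSE]
    rl <- nchar(r$seq)
    keep <- r$pos <= win_e & (r$pos + rl - 1L) >= win_s
    r <- r[keep, , drop = FALSE]; rl <- rl[keep]
    if (nrow(r)) {
      s_off <- pmax(r$pos, win_s) - win_s + 1L
      e_off <- pmin(r$pos + rl - 1L, win_e) - win_s + 1L
      cov <- IRanges::coverage(IRanges::IRanges(start = s_off, end = e_off),
                               width = wlen)
      depth <- as.integer(cov)
      st <- r$pos - win_s + 1L
      st <- st[st >= 1L & st <= wlen]
      starts <- tabulate(st, nbins = wlen)
    }
  }
  structure(list(locus = locus_id, chrom = annotation$chrom[i],
                 window_start = win_s, window_end = win_e,
                 locus_start = annotation$start[i],
                 locus_end = annotation$end[i],
                 strand = annotation$strand[i],
                 depth = depth, starts = starts,
                 n_reads = sum(starts)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$locus, "window", x$window_start, "-",
      x$window_end, ";", x$n_reads, "primary read starts; mean depth",
      sprintf("%.1f", mean(x$depth)), "\n")
  invisible(x)
}

# start enrichment at a genomic TSS: observed starts within +/- window
# over the expectation under uniform starts across the covered span
start_enrichment <- function(profile, tss, window = 50L) {
  if (profile$n_reads == 0L) return(0)
  covered <- sum(profile$depth > 0L)
  if (covered == 0L) return(0)
  lo <- max(profile$window_start, tss - window)
  hi <- min(profile$window_end, tss + window)
  if (lo > hi) return(0)
  obs <- sum(profile$starts[(lo:hi) - profile$window_start + 1L])
  expected <- profile$n_reads * (hi - lo + 1L) / covered
  if (expected == 0) return(0)
  obs / expected
}

# mean depth over a genomic interval (clipped to the window)
mean_depth <- function(profile, lo, hi) {
  lo <- max(lo, profile$window_start); hi <- min(hi, profile$window_end)
  if (lo > hi) return(0)
  mean(profile$depth[(lo:hi) - profile$window_start + 1L])
}

#' Classify the transcription mechanism of a provirus
#'
#' Computes a start-enrichment ratio at each candidate transcription
#' start site (the provirus's own 5' LTR U3-R border and the U3-R
#' border of any annotated upstream solo LTR) and an
#' upstream-continuity ratio (mean depth in the upstream flank over
#' mean internal depth). Calls `ltr_driven` when start enrichment
#' reaches `enrichment_min` with no upstream continuity (attributing
#' the drive to the element whose TSS is enriched), `read_through`
#' when coverage continues in from upstream, `indeterminate`
#' otherwise, and `silent` for unexpressed loci.
#'
#' @param profile A [coverage_profile()].
#' @param annotation Locus annotation table.
#' @param expressed Logical: is the locus expressed (e.g. tissue mean
#'   TPM at or above 1)?
#' @param tss_window Half-width (nt) of the TSS start window.
#' @param enrichment_min Minimum start-enrichment ratio for an
#'   LTR-driven call.
#' @param continuity_ltr Maximum upstream-continuity ratio compatible
#'   with LTR-driven transcription.
#' @param continuity_rt Minimum upstream-continuity ratio for a
#'   read-through call.
#' @param upstream_flank Upstream window (nt) for the continuity
#'   ratio.
#' @param solo_search Distance (nt) within which upstream solo LTRs
#'   are considered candidate drivers.
#' @return One-row data.frame: `locus_id`, `call`, `driver`,
#'   `start_enrichment`, `upstream_continuity`.
#' @export
classify_mechanism <- function(profile, annotation, expressed = TRUE,
                               tss_window = 50L, enrichment_min = 5,
                               continuity_ltr = 0.2, continuity_rt = 0.8,
                               upstream_flank = 500L,
                               solo_search = 2000L) {
  i <- match(profile$locus, annotation$locus_id)
  row <- annotation[i, ]
  out <- function(call, driver, enr = NA_real_, cont = NA_real_)
    data.frame(locus_id = profile$locus, call = call, driver = driver,
               start_enrichment = enr, upstream_continuity = cont,
               stringsAsFactors = FALSE)
  if (!isTRUE(expressed)) return(out("silent", NA_character_))

  plus <- row$strand == "+"
  internal <- mean_depth(profile, row$start, row$end)
  up_lo <- if (plus) row$start - upstream_flank else row$end + 1L
  up_hi <- if (plus) row$start - 1L else row$end + upstream_flank
  continuity <- if (internal > 0) mean_depth(profile, up_lo, up_hi) / internal
                else 0

  # candidate TSSs: own 5' LTR, then upstream solo LTRs
  cand <- list()
  if (!is.na(row$ltr5_start)) {
    tss <- if (plus) row$ltr5_start + (LTR_U3[2] + 1L) - 1L
           else row$ltr5_end - (LTR_U3[2] + 1L) + 1L
    cand[["5ltr"]] <- tss
  }
  solos <- annotation[annotation$class == "solo_LTR" &
                        annotation$chrom == row$chrom, , drop = FALSE]
  if (nrow(solos)) {
    for (k in seq_len(nrow(solos))) {
      gap <- if (plus) row$start - solos$end[k]
             else solos$start[k] - row$end
      if (gap > 0L && gap <= solo_search) {
        tss <- if (plus) solos$start[k] + (LTR_U3[2] + 1L) - 1L
               else solos$end[k] - (LTR_U3[2] + 1L) + 1L
        cand[[solos$locus_id[k]]] <- tss
      }
    }
  }
  enr <- vapply(cand, function(t) start_enrichment(profile, t, tss_window), 1)

  if (length(enr) && "5ltr" %in% names(enr) &&
      enr[["5ltr"]] >= enrichment_min && continuity <= continuity_ltr)
    return(out("ltr_driven", "5ltr", enr[["5ltr"]], continuity))
  solo_enr <- enr[setdiff(names(enr), "5ltr")]
  if (length(solo_enr) && max(solo_enr) >= enrichment_min) {
    drv <- names(solo_enr)[which.max(solo_enr)]
    # continuity measured beyond the driving solo LTR
    j <- match(drv, annotation$locus_id)
    b_lo <- if (plus) annotation$start[j] - upstream_flank
            else annotation$end[j] + 1L
    b_hi <- if (plus) annotation$start[j] - 1L
            else annotation$end[j] + upstream_flank
    cont2 <- if (internal > 0) mean_depth(profile, b_lo, b_hi) / internal
             else 0
    if (cont2 <= continuity_ltr)
      return(out("ltr_driven", drv, max(solo_enr), continuity))
  }
  if (continuity >= continuity_rt)
    return(out("read_through", "upstream_transcript",
               if (length(enr)) max(enr) else 0, continuity))
  out("indeterminate", NA_character_,
      if (length(enr)) max(enr) else 0, continuity)
}

#' Correlate provirus expression with neighbouring gene expression
#'
#' Pearson correlation of `log2(TPM + 1)` between each expressed
#' provirus and every host gene within `window` nt, across samples,
#' with Benjamini-Hochberg adjustment; flags proviruses contained in a
#' gene interval (intronic).
#'
#' @param em An `expression_matrix` containing both proviruses and
#'   host genes.
#' @param window Maximum gap (nt) between provirus and gene (default
#'   10 kb).
#' @param min_samples Minimum number of samples required.
#' @return data.frame: `provirus`, `gene`, `distance`, `contained`,
#'   `r`, `p`, `p_adj`.
#' @export
neighbor_gene_correlation <- function(em, window = 10000L,
                                      min_samples = 3L) {
  ann <- em$annotation
  pv <- ann[ann$class == "provirus", , drop = FALSE]
  hg <- ann[ann$class == "host_gene", , drop = FALSE]
  if (ncol(em$tpm) < min_samples)
    stop("need >= ", min_samples, " samples")
  rows <- list()
  for (i in seq_len(nrow(pv))) for (j in seq_len(nrow(hg))) {
    if (pv$chrom[i] != hg$chrom[j]) next
    gap <- max(pv$start[i], hg$start[j]) - min(pv$end[i], hg$end[j])
    gap <- max(0L, gap)
    if (gap > window) next
    x <- log2(em$tpm[pv$locus_id[i], ] + 1)
    y <- log2(em$tpm[hg$locus_id[j], ] + 1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant expression vector for pair ", pv$locus_id[i],
              " / ", hg$locus_id[j], "; correlation NA")
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      provirus = pv$locus_id[i], gene = hg$locus_id[j],
      distance = gap,
      contained = pv$start[i] >= hg$start[j] & pv$end[i] <= hg$end[j],
      r = r, p = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(provirus = character(), gene = character(),
                      distance = integer(), contained = logical(),
                      r = numeric(), p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
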