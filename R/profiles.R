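# Expression profiling: per-tissue totals, per-provirus tissue
# patterns, provirus-age (ESA) breakdowns and covariate comparisons.

provirus_rows <- function(em) {
  em$annotation$locus_id[em$annotation$class == "provirus"]
}

#' Per-sample and per-tissue total HML-2 expression
#'
#' Sums provirus TPM per sample and summarises the distribution per
#' tissue (quartiles, 1.5 x IQR whiskers, outlier count), alongside
#' expressed-provirus counts at the given threshold.
#'
#' @param em An [quantify_cohort()] `expression_matrix`.
#' @param threshold Expression-calling threshold in TPM.
#' @return A list with `samples` (per-sample totals) and `tissues`
#'   (per-tissue summary data.frame).
#' @export
tissue_summary <- function(em, threshold = 1) {
  pv <- provirus_rows(em)
  totals <- colSums(em$tpm[pv, , drop = FALSE])
  md <- em$metadata[match(names(totals), em$metadata$sample), ]
  samples <- data.frame(sample = names(totals), tissue = md$tissue,
                        total_tpm = as.numeric(totals),
                        stringsAsFactors = FALSE)
  calls <- call_expressed(em$tpm[pv, , drop = FALSE], em$metadata,
                          threshold = threshold)
  tissues <- do.call(rbind, lapply(unique(samples$tissue), function(tt) {
    x <- samples$total_tpm[samples$tissue == tt]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    data.frame(tissue = tt, n_samples = length(x), mean_total = mean(x),
               q1 = q[1], median = q[2], q3 = q[3],
               whisker_low = max(min(x), lo), whisker_high = min(max(x), hi),
               n_outliers = sum(x < lo | x > hi),
               n_expressed = unname(calls$per_tissue_counts[tt]),
               stringsAsFactors = FALSE)
  }))
  rownames(tissues) <- NULL
  list(samples = samples, tissues = tissues)
}

#' Classify per-provirus tissue expression patterns
#'
#' Three patterns: `ubiquitous` (expressed in at least
#' `ubiquitous_frac` of tissues), `type_restricted` (every expressing
#' tissue shares one tissue type), `mixed` (several types, below the
#' ubiquitous fraction); loci expressed nowhere are `silent`.
#'
#' @param expressed Logical loci x tissues matrix
#'   ([call_expressed()]`$expressed`).
#' @param tissue_types Named character vector tissue -> tissue type
#'   (e.g. brain, reproductive, circulatory).
#' @param ubiquitous_frac Fraction of tissues quantifying "almost all"
#'   (default 0.9).
#' @return Named character vector of pattern labels per locus.
#' @export
pattern_classify <- function(expressed, tissue_types,
                             ubiquitous_frac = 0.9) {
  miss <- setdiff(colnames(expressed), names(tissue_types))
  if (length(miss))
    stop("tissue(s) missing from tissue_types: ", paste(miss, collapse = ", "))
  apply(expressed, 1L, function(e) {
    if (!any(e)) return("silent")
    frac <- mean(e)
    if (frac >= ubiquitous_frac) return("ubiquitous")
    types <- unique(tissue_types[colnames(expressed)[e]])
    if (length(types) == 1L) "type_restricted" else "mixed"
  })
}

#' Expression by provirus age (earliest shared ancestor) group
#'
#' Per tissue and ESA group: mean total group TPM across samples, the
#' group-size-normalised share of total expression (in percent,
#' summing to 100 within a tissue), the fraction of group members
#' expressed above 1 TPM, and Tukey HSD pairwise comparisons between
#' groups (on per-provirus within-tissue mean TPM).
#'
#' @param em An `expression_matrix`.
#' @param tissues Tissues of interest (default: all).
#' @return A list with `breakdown` (tissue x group table) and `tukey`
#'   (pairwise comparison table with adjusted p-values).
#' @export
esa_breakdown <- function(em, tissues = NULL) {
  ann <- em$annotation
  pv <- ann[ann$class == "provirus", ]
  if (anyNA(pv$esa_group)) stop("provirus without esa_group annotation")
  md <- em$metadata
  tissues <- tissues %||% unique(md$tissue)
  groups <- unique(pv$esa_group)
  empty <- setdiff(ESA_GROUPS, groups)

  rows <- list(); tukey <- list()
  for (tt in tissues) {
    ss <- md$sample[md$tissue == tt]
    if (!length(ss)) { warning("tissue without samples: ", tt); next }
    tpm_t <- em$tpm[pv$locus_id, ss, drop = FALSE]
    locus_mean <- rowMeans(tpm_t)
    for (g in groups) {
      members <- pv$locus_id[pv$esa_group == g]
      gm <- em$tpm[members, ss, drop = FALSE]
      group_total_mean <- mean(colSums(gm))
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tt, esa_group = g, n_proviruses = length(members),
        mean_total_tpm = group_total_mean,
        per_provirus_mean = group_total_mean / length(members),
        frac_expressed = mean(locus_mean[members] > 1),
        stringsAsFactors = FALSE)
    }
    # group-size-normalised share of total expression
    idx <- (length(rows) - length(groups) + 1L):length(rows)
    pp <- vapply(rows[idx], `[[`, 1, "per_provirus_mean")
    tot <- sum(pp)
    share <- if (tot > 0) 100 * pp / tot else rep(NA_real_, length(pp))
    for (k in seq_along(idx)) rows[[idx[k]]]$share_pct <- share[k]
    # Tukey HSD between ESA groups on per-provirus mean TPM
    df <- data.frame(y = locus_mean,
                     g = factor(pv$esa_group[match(names(locus_mean),
                                                   pv$locus_id)]))
    if (nlevels(df$g) >= 2L && all(table(df$g) >= 2L)) {
      fit <- stats::aov(y ~ g, data = df)
      tk <- stats::TukeyHSD(fit)$g
      tukey[[tt]] <- data.frame(tissue = tt,
                                comparison = rownames(tk),
                                diff = tk[, "diff"],
                                p_adj = tk[, "p adj"],
                                row.names = NULL,
                                stringsAsFactors = FALSE)
    }
  }
  breakdown <- do.call(rbind, rows)
  rownames(breakdown) <- NULL
  list(breakdown = breakdown,
       tukey = if (length(tukey)) do.call(rbind, c(tukey,
                                                   make.row.names = FALSE))
               else NULL,
       excluded_groups = empty)
}

#' Covariate comparisons of provirus expression
#'
#' Per provirus and tissue, compares `log2(TPM + 1)` between covariate
#' groups: Welch's t-test for two groups, one-way ANOVA (plus Tukey
#' HSD) for more. P-values are Benjamini-Hochberg adjusted within each
#' tissue x covariate family.
#'
#' @param em An `expression_matrix`.
#' @param covariate One of `"sex"`, `"age_group"`, `"hardy"`.
#' @param tissues Tissues of interest (default: all).
#' @param alpha Significance level (default 0.05).
#' @param min_group_size Groups smaller than this are dropped.
#' @return A list with `tests` (per locus x tissue results) and
#'   `group_means` (long table of group means).
#' @export
covariate_tests <- function(em, covariate = c("sex", "age_group", "hardy"),
                            tissues = NULL, alpha = 0.05,
                            min_group_size = 2L) {
  covariate <- match.arg(covariate)
  md <- em$metadata
  tissues <- tissues %||% unique(md$tissue)
  pv <- provirus_rows(em)
  tests <- list(); means <- list(); tukeys <- list()
  for (tt in tissues) {
    mt <- md[md$tissue == tt, ]
    tab <- table(mt[[covariate]])
    keep_groups <- names(tab)[tab >= min_group_size]
    if (length(keep_groups) < 2L) {
      warning("tissue ", tt, ": fewer than 2 usable ", covariate,
              " groups; skipped")
      next
    }
    mt <- mt[mt[[covariate]] %in% keep_groups, ]
    g <- factor(mt[[covariate]])
    y_all <- log2(em$tpm[pv, mt$sample, drop = FALSE] + 1)
    res_t <- lapply(pv, function(lc) {
      y <- y_all[lc, ]
      gm <- tapply(y, g, mean)
      v <- tapply(y, g, stats::var)
      if (all(v == 0 | is.na(v))) {
        p <- NA_real_; stat <- NA_real_
        warning("zero within-group variance for ", lc, " in ", tt)
      } else if (nlevels(g) == 2L) {
        ht <- stats::t.test(y ~ g)          # Welch by default
        p <- ht$p.value; stat <- unname(ht$statistic)
      } else {
        fit <- stats::aov(y ~ g)
        s <- summary(fit)[[1]]
        p <- s[["Pr(>F)"]][1]; stat <- s[["F value"]][1]
        tk <- stats::TukeyHSD(fit)$g
        tukey_df <- data.frame(locus_id = lc, tissue = tt,
                               comparison = rownames(tk),
                               diff = tk[, "diff"], p_adj = tk[, "p adj"],
                               row.names = NULL, stringsAsFactors = FALSE)
      }
      list(row = data.frame(locus_id = lc, tissue = tt,
                            covariate = covariate, statistic = stat,
                            p = p, stringsAsFactors = FALSE),
           means = data.frame(locus_id = lc, tissue = tt,
                              group = names(gm), mean_log2_tpm = as.numeric(gm),
                              stringsAsFactors = FALSE),
           tukey = if (exists("tukey_df", inherits = FALSE)) tukey_df
                   else NULL)
    })
    fam <- do.call(rbind, lapply(res_t, `[[`, "row"))
    fam$p_adj <- stats::p.adjust(fam$p, method = "BH")
    tests[[tt]] <- fam
    means[[tt]] <- do.call(rbind, lapply(res_t, `[[`, "means"))
    tk_all <- Filter(Negate(is.null), lapply(res_t, `[[`, "tukey"))
    if (length(tk_all))
      tukeys[[tt]] <- do.call(rbind, c(tk_all, make.row.names = FALSE))
  }
  tests <- if (length(tests)) do.call(rbind, c(tests, make.row.names = FALSE))
           else NULL
  if (!is.null(tests)) tests$significant <- !is.na(tests$p_adj) &
      tests$p_adj < alpha
  list(tests = tests,
       group_means = if (length(means))
         do.call(rbind, c(means, make.row.names = FALSE)) else NULL,
       tukey = if (length(tukeys))
         do.call(rbind, c(tukeys, make.row.names = FALSE)) else NULL,
       alpha = alpha)
}
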