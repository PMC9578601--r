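# RNA-seq read simulation. Reads are drawn from transcript units
# (LTR-driven: the U3-R border of the driving LTR through the 3' R-U5
# border; read-through: a window starting upstream of the provirus and
# running through it; host genes: the gene interval), with expected
# counts proportional to abundance x unit length. Every read is then
# placed at all homologous genomic locations within a mismatch budget
# by exact scan of the planted copies (including 5'/3' LTR
# cross-homology), and emitted as SAM records with alignment scores;
# exactly one record per read -- the true source -- is primary.

#' Describe a simulated sample
#'
#' @param sample_id,donor_id,tissue Sample identifiers.
#' @param sex `"M"` or `"F"`.
#' @param age Donor age in years, 20-70.
#' @param hardy Death-rapidity score, 1 (fastest) to 4 (slowest).
#' @param expression Named numeric vector: expected transcript
#'   abundance (arbitrary units) per locus_id.
#' @param library_size Number of reads to simulate.
#' @param read_length Read length in nt (>= 75 by default convention).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed for this sample's reads.
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(sample_id, donor_id, tissue, sex = "F", age = 50L,
                          hardy = 2L, expression, library_size = 10000L,
                          read_length = 75L, error_rate = 0.001, seed = 1L) {
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  age <- as.integer(age)
  if (is.na(age) || age < 20L || age > 70L)
    stop("age must be in [20, 70] (cohort range), got ", age)
  hardy <- as.integer(hardy)
  if (is.na(hardy) || !hardy %in% 1:4)
    stop("hardy score must be in 1..4, got ", hardy)
  if (is.null(names(expression)) || any(!nzchar(names(expression))))
    stop("expression must be a named vector (locus_id -> abundance)")
  if (any(expression < 0)) stop("abundances must be >= 0")
  if (as.integer(library_size) < 0L) stop("library_size must be >= 0")
  structure(
    list(sample_id = sample_id, donor_id = donor_id, tissue = tissue,
         sex = sex, age = age, hardy = hardy,
         expression = expression,
         library_size = as.integer(library_size),
         read_length = as.integer(read_length),
         error_rate = error_rate, seed = as.integer(seed)),
    class = "sample_design")
}

age_group <- function(age) {
  cut(age, breaks = c(19L, 35L, 51L, 70L),
      labels = c("20-35", "35-51", "52-70"))
}

#' Write sample metadata to TSV
#'
#' Emits columns `sample`, `donor`, `tissue`, `sex`, `age`,
#' `age_group`, `hardy`; age groups are 20-35, 35-51 and 52-70 (ages
#' <= 35 fall in the youngest bin).
#'
#' @param designs List of [sample_design()] objects.
#' @param path Output TSV path (optional).
#' @return The metadata data.frame, invisibly if written.
#' @export
emit_metadata <- function(designs, path = NULL) {
  ids <- vapply(designs, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  md <- data.frame(
    sample = ids,
    donor = vapply(designs, `[[`, "", "donor_id"),
    tissue = vapply(designs, `[[`, "", "tissue"),
    sex = vapply(designs, `[[`, "", "sex"),
    age = vapply(designs, `[[`, 1L, "age"),
    hardy = vapply(designs, `[[`, 1L, "hardy"),
    stringsAsFactors = FALSE
  )
  md$age_group <- as.character(age_group(md$age))
  md <- md[, c("sample", "donor", "tissue", "sex", "age", "age_group", "hardy")]
  if (!is.null(path)) {
    write_units_tsv(md, path, "sample metadata; age in years; hardy 1-4")
    return(invisible(md))
  }
  md
}

# ---- transcript units -------------------------------------------------

# genomic transcript unit per expressed locus
transcript_units <- function(genome, locus_ids, rt_upstream = 1500L) {
  ann <- genome$annotation
  out <- lapply(locus_ids, function(id) {
    i <- match(id, ann$locus_id)
    if (is.na(i)) stop("unknown locus in expression vector: ", id)
    row <- ann[i, ]
    lc <- genome$loci[[id]]
    if (row$class == "host_gene" || row$class == "solo_LTR")
      return(list(locus = id, ustart = row$start, uend = row$end,
                  tss = NA_integer_, mechanism = "host"))
    # provirus
    map <- lc$map
    l3 <- map_template_span(map, LTR3_REGION[1], LTR3_REGION[2])
    if (is.na(l3)) stop("provirus ", id, " lacks a 3' LTR; no poly(A) site")
    polyA_l <- l3 + (LTR_R[2] - 1L)            # R-U5 border (last R base)
    polyA_g <- if (row$strand == "+") row$start + polyA_l - 1L
               else row$end - polyA_l + 1L
    if (row$mechanism == "read_through") {
      if (row$strand == "+")
        return(list(locus = id, ustart = max(1L, row$start - rt_upstream),
                    uend = row$end, tss = NA_integer_,
                    mechanism = "read_through"))
      return(list(locus = id, ustart = row$start,
                  uend = row$end + rt_upstream, tss = NA_integer_,
                  mechanism = "read_through"))
    }
    # LTR-driven: own 5' LTR, or an annotated upstream solo LTR driver
    if (!is.na(row$upstream_driver)) {
      j <- match(row$upstream_driver, ann$locus_id)
      solo <- ann[j, ]
      tss_g <- if (solo$strand == "+") solo$start + (LTR_U3[2] + 1L) - 1L
               else solo$end - (LTR_U3[2] + 1L) + 1L
      if (row$strand == "+")
        return(list(locus = id, ustart = tss_g, uend = polyA_g,
                    tss = tss_g, mechanism = "ltr_driven"))
      return(list(locus = id, ustart = polyA_g, uend = tss_g,
                  tss = tss_g, mechanism = "ltr_driven"))
    }
    l5 <- map_template_span(map, LTR5_REGION[1], LTR5_REGION[2])
    if (is.na(l5))
      stop("provirus ", id, " is marked ltr_driven but has no 5' LTR ",
           "and no upstream driver")
    tss_l <- l5 + (LTR_U3[2] + 1L) - 1L        # first R base
    tss_g <- if (row$strand == "+") row$start + tss_l - 1L
             else row$end - tss_l + 1L
    if (row$strand == "+")
      list(locus = id, ustart = tss_g, uend = polyA_g, tss = tss_g,
           mechanism = "ltr_driven")
    else
      list(locus = id, ustart = polyA_g, uend = tss_g, tss = tss_g,
           mechanism = "ltr_driven")
  })
  units <- do.call(rbind, lapply(out, function(u)
    data.frame(locus = u$locus, ustart = u$ustart, uend = u$uend,
               tss = u$tss, mechanism = u$mechanism,
               stringsAsFactors = FALSE)))
  units$chrom <- ann$chrom[match(units$locus, ann$locus_id)]
  units$strand <- ann$strand[match(units$locus, ann$locus_id)]
  units$length <- units$uend - units$ustart + 1L
  units
}

# ---- simulation -------------------------------------------------------

#' Simulate multimapping RNA-seq alignments for one sample
#'
#' @param genome An [build_genome()] result.
#' @param design A [sample_design()].
#' @param sam_path Optional path; when given, a valid SAM file is
#'   written.
#' @param truth_path Optional path for the hidden truth TSV (read,
#'   true source locus, unit type, position).
#' @param mismatch_budget Maximum mismatches for a candidate location
#'   (default 3 of a 75-nt read).
#' @param tss_fraction Fraction of reads of an LTR-driven unit that
#'   start within `tss_jitter` nt of the U3-R border, emulating the
#'   transcription-start pile-up seen in read alignments.
#' @param tss_jitter Width (nt) of the start pile-up window.
#' @param rt_upstream Upstream window length for read-through units.
#' @return A list with `records` (SAM fields data.frame), `truth`
#'   (data.frame), `chrom_lengths`, and the paths written (or `NULL`).
#' @export
simulate_reads <- function(genome, design, sam_path = NULL,
                           truth_path = NULL, mismatch_budget = 3L,
                           tss_fraction = 0.15, tss_jitter = 50L,
                           rt_upstream = 1500L) {
  stopifnot(inherits(genome, "hml2_genome"), inherits(design, "sample_design"))
  expr <- design$expression
  L <- design$read_length
  chrom_lengths <- vapply(genome$chroms, nchar, 1L)

  if (design$library_size > 0L && sum(expr) <= 0)
    stop("total abundance is zero but library_size > 0")

  empty <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), as = integer(),
                      stringsAsFactors = FALSE)
  empty_truth <- data.frame(read = character(), sample = character(),
                            locus = character(), unit = character(),
                            chrom = character(), pos = integer(),
                            strand = character(), stringsAsFactors = FALSE)
  if (design$library_size == 0L || sum(expr) <= 0) {
    if (!is.null(sam_path)) write_sam(empty, chrom_lengths, sam_path)
    if (!is.null(truth_path))
      write_units_tsv(empty_truth, truth_path, "simulation ground truth")
    return(list(records = empty, truth = empty_truth,
                chrom_lengths = chrom_lengths,
                sam_path = sam_path, truth_path = truth_path))
  }

  units <- transcript_units(genome, names(expr), rt_upstream = rt_upstream)
  if (any(units$length < L))
    stop("transcript unit shorter than the read length: ",
         units$locus[units$length < L][1])

  res <- with_seed(design$seed, {
    w <- expr * units$length
    counts <- as.vector(stats::rmultinom(1L, design$library_size, w))

    src_locus <- rep(units$locus, counts)
    src_chrom <- rep(units$chrom, counts)
    src_mech <- rep(units$mechanism, counts)
    n <- length(src_locus)

    # start positions (uniform over the unit, with a TSS-proximal
    # mixture component for LTR-driven units)
    starts <- integer(n)
    idx0 <- 0L
    for (u in seq_len(nrow(units))) {
      k <- counts[u]
      if (k == 0L) next
      lo <- units$ustart[u]; hi <- units$uend[u] - L + 1L
      s <- lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
      if (units$mechanism[u] == "ltr_driven" && !is.na(units$tss[u]) &&
          tss_fraction > 0) {
        at_tss <- stats::runif(k) < tss_fraction
        m <- sum(at_tss)
        if (m > 0L) {
          if (units$strand[u] == "+") {
            s[at_tss] <- units$tss[u] +
              sample.int(tss_jitter + 1L, m, replace = TRUE) - 1L
          } else {
            s[at_tss] <- units$tss[u] - L + 1L -
              (sample.int(tss_jitter + 1L, m, replace = TRUE) - 1L)
          }
        }
      }
      starts[idx0 + seq_len(k)] <- s
      idx0 <- idx0 + k
    }

    qname <- sprintf("%s_r%06d", design$sample_id, seq_len(n))

    # read byte matrix from the forward genome
    chrom_raw <- lapply(genome$chroms, charToRaw)
    reads <- matrix(as.raw(0L), n, L)
    for (ch in unique(src_chrom)) {
      sel <- src_chrom == ch
      idx <- outer(starts[sel] - 1L, seq_len(L), `+`)
      reads[sel, ] <- chrom_raw[[ch]][idx]
    }

    # sequencing errors: substitution to a different base
    err_n <- stats::rbinom(n, L, design$error_rate)
    err_rows <- which(err_n > 0L)
    for (r in err_rows) {
      p <- sample.int(L, err_n[r])
      old <- rawToChar(reads[r, p], multiple = TRUE)
      new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      reads[r, p] <- charToRaw(paste(new, collapse = ""))
    }

    # ---- candidate locations by exact homologous scan ----
    ann <- genome$annotation
    feat <- ann[ann$class %in% c("provirus", "solo_LTR"), , drop = FALSE]
    # template span of each read within its source locus (NA if the
    # window leaves the locus or crosses a non-template junction)
    t1 <- rep(NA_integer_, n)
    src_is_feat <- src_locus %in% feat$locus_id
    for (id in unique(src_locus[src_is_feat])) {
      i <- match(id, ann$locus_id)
      sel <- which(src_locus == id)
      within <- starts[sel] >= ann$start[i] &
        (starts[sel] + L - 1L) <= ann$end[i]
      sel <- sel[within]
      if (!length(sel)) next
      lc <- genome$loci[[id]]
      l1 <- if (ann$strand[i] == "+") starts[sel] - ann$start[i] + 1L
            else ann$end[i] - (starts[sel] + L - 1L) + 1L
      tp1 <- lc$tpos[l1]; tp2 <- lc$tpos[l1 + L - 1L]
      ok <- !is.na(tp1) & !is.na(tp2) & (tp2 - tp1 == L - 1L)
      t1[sel[ok]] <- tp1[ok]
    }

    # candidate (read, locus, variant) tuples
    cand <- list()
    add_cand <- function(rows, tstarts, target_i) {
      # rows: read indices; tstarts: template start of the span to
      # look up in target locus target_i (annotation row index)
      id <- ann$locus_id[target_i]
      lc <- genome$loci[[id]]
      map <- lc$map
      l1k <- rep(NA_integer_, length(rows))
      for (s in seq_len(nrow(map))) {
        hit <- tstarts >= map$tstart[s] & (tstarts + L - 1L) <= map$tend[s]
        l1k[hit] <- map$lstart[s] + (tstarts[hit] - map$tstart[s])
      }
      ok <- !is.na(l1k)
      if (!any(ok)) return(NULL)
      rows <- rows[ok]; l1k <- l1k[ok]
      gpos <- if (ann$strand[target_i] == "+") ann$start[target_i] + l1k - 1L
              else ann$end[target_i] - (l1k + L - 1L) + 1L
      flip <- ann$strand[target_i] != ann$strand[match(src_locus[rows],
                                                      ann$locus_id)]
      # source strand for reads from host/background units: '+'
      flip[is.na(flip)] <- ann$strand[target_i] == "-"
      data.frame(row = rows, target = target_i, gpos = gpos, flip = flip)
    }

    have_span <- which(!is.na(t1))
    for (fi in seq_len(nrow(feat))) {
      target_i <- match(feat$locus_id[fi], ann$locus_id)
      variants <- list(t1[have_span])
      in5 <- t1[have_span] >= LTR5_REGION[1] &
        (t1[have_span] + L - 1L) <= LTR5_REGION[2]
      in3 <- t1[have_span] >= LTR3_REGION[1] &
        (t1[have_span] + L - 1L) <= LTR3_REGION[2]
      if (any(in5))
        variants <- c(variants, list(ifelse(in5, t1[have_span] + LTR3_OFFSET,
                                            NA_integer_)))
      if (any(in3))
        variants <- c(variants, list(ifelse(in3, t1[have_span] - LTR3_OFFSET,
                                            NA_integer_)))
      for (v in variants) {
        keep <- !is.na(v)
        if (!any(keep)) next
        cc <- add_cand(have_span[keep], v[keep], target_i)
        if (!is.null(cc)) cand[[length(cand) + 1L]] <- cc
      }
    }
    cand <- if (length(cand)) do.call(rbind, cand) else
      data.frame(row = integer(), target = integer(), gpos = integer(),
                 flip = logical())
    # drop the self candidate (the source record is added separately)
    self <- cand$gpos == starts[cand$row] &
      ann$chrom[cand$target] == src_chrom[cand$row]
    cand <- cand[!self, , drop = FALSE]

    # mismatch counts for candidates, vectorised per (chrom, flip)
    mm <- integer(nrow(cand))
    if (nrow(cand)) {
      cand_chrom <- ann$chrom[cand$target]
      for (ch in unique(cand_chrom)) {
        for (fl in c(FALSE, TRUE)) {
          sel <- which(cand_chrom == ch & cand$flip == fl)
          if (!length(sel)) next
          rm_ <- reads[cand$row[sel], , drop = FALSE]
          if (fl) rm_ <- t(apply(rm_, 1L, revcomp_raw))
          mm[sel] <- .window_mismatch_cpp(chrom_raw[[ch]], cand$gpos[sel], rm_)
        }
      }
    }
    keep <- !is.na(mm) & mm <= mismatch_budget
    cand <- cand[keep, , drop = FALSE]
    mm <- mm[keep]
    # deduplicate (same read, same genomic position reachable through
    # two homology variants)
    key <- paste(cand$row, cand$target, cand$gpos)
    dup <- duplicated(key)
    cand <- cand[!dup, , drop = FALSE]; mm <- mm[!dup]

    # assemble records: primary (source) + secondary candidates
    seq_fwd <- apply(reads, 1L, rawToChar)
    n_sec_per_read <- tabulate(cand$row, nbins = n)
    prim <- data.frame(
      qname = qname, flag = 0L, rname = src_chrom, pos = starts,
      mapq = ifelse(n_sec_per_read > 0L, 1L, 60L),
      cigar = sprintf("%dM", L), seq = seq_fwd,
      as = -6L * err_n, stringsAsFactors = FALSE)
    if (nrow(cand)) {
      seq_sec <- seq_fwd[cand$row]
      if (any(cand$flip))
        seq_sec[cand$flip] <- vapply(seq_sec[cand$flip], revcomp, "")
      sec <- data.frame(
        qname = qname[cand$row],
        flag = SAM_FLAG_SECONDARY + ifelse(cand$flip, SAM_FLAG_REVERSE, 0L),
        rname = ann$chrom[cand$target], pos = cand$gpos,
        mapq = 1L, cigar = sprintf("%dM", L), seq = seq_sec,
        as = -6L * mm, stringsAsFactors = FALSE)
      records <- rbind(prim, sec)
    } else records <- prim
    records <- records[order(records$rname, records$pos, records$qname,
                             records$flag), ]
    rownames(records) <- NULL

    truth <- data.frame(
      read = qname, sample = design$sample_id, locus = src_locus,
      unit = src_mech, chrom = src_chrom, pos = starts,
      strand = ann$strand[match(src_locus, ann$locus_id)],
      stringsAsFactors = FALSE)
    truth$strand[is.na(truth$strand)] <- "+"
    list(records = records, truth = truth)
  })

  if (!is.null(sam_path)) write_sam(res$records, chrom_lengths, sam_path)
  if (!is.null(truth_path))
    write_units_tsv(res$truth, truth_path,
                    "simulation ground truth; pos 1-based")
  list(records = res$records, truth = res$truth,
       chrom_lengths = chrom_lengths,
       sam_path = sam_path, truth_path = truth_path)
}
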