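# ORF intactness annotation. Each provirus is aligned globally to the
# full-length reference; the reference gene intervals are projected
# through the alignment onto the provirus; each projected segment is
# scanned for premature stop codons, frameshifting indels and missing
# subintervals; finally provirus-level context rules are applied (pro
# and pol must be translatable in the context of the GagProPol
# polyprotein; type 1 proviruses cannot express env or rec and are
# evaluated for np9 instead).

#' Global pairwise alignment of a provirus to the reference
#'
#' Banded Needleman-Wunsch with affine gaps (match +2, mismatch -3,
#' gap open -5, gap extend -2 by default, the scale of the package's
#' coordinate projection). Tie-breaking is deterministic (gaps placed
#' as left-anchored runs).
#'
#' @param provirus,reference DNA strings (A/C/G/T only).
#' @param match,mismatch Base match/mismatch scores.
#' @param gap_open,gap_extend Gap penalties (positive costs); a gap of
#'   length L costs `gap_open + gap_extend * L`.
#' @param band Extra band width around the length-difference diagonal.
#' @return An object of class `pairwise_alignment`: list with the
#'   gapped strings `provirus`/`reference`, `score`, `identity` and
#'   per-column coordinate maps `ref_pos`, `prov_pos` (0 at gap
#'   columns).
#' @export
align_to_reference <- function(provirus, reference, match = 2,
                               mismatch = -3, gap_open = 5,
                               gap_extend = 2, band = NULL) {
  if (!nzchar(provirus)) stop("provirus sequence is empty")
  if (!nzchar(reference)) stop("reference sequence is empty")
  assert_dna(provirus, "provirus sequence")
  assert_dna(reference, "reference sequence")
  if (is.null(band))
    band <- abs(nchar(provirus) - nchar(reference)) + 400L
  res <- .align_affine_cpp(provirus, reference, match, mismatch,
                           gap_open, gap_extend, as.integer(band))
  pa <- strsplit(res$a, "")[[1]]
  ra <- strsplit(res$b, "")[[1]]
  prov_pos <- cumsum(pa != "-"); prov_pos[pa == "-"] <- 0L
  ref_pos <- cumsum(ra != "-"); ref_pos[ra == "-"] <- 0L
  both <- pa != "-" & ra != "-"
  structure(list(provirus = res$a, reference = res$b, score = res$score,
                 identity = sum(pa[both] == ra[both]) / sum(both),
                 prov_chars = pa, ref_chars = ra,
                 prov_pos = prov_pos, ref_pos = ref_pos),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment: score", x$score, ", identity",
      sprintf("%.2f%%", 100 * x$identity), ",", length(x$prov_chars),
      "columns\n")
  invisible(x)
}

#' Project reference gene intervals onto a provirus
#'
#' Maps each gene part's reference interval through the alignment,
#' extracts the provirus sequence over it (including inserted bases),
#' and records deletion and insertion events in segment coordinates.
#' Spliced genes (rec, np9) concatenate their parts 5' to 3'.
#'
#' @param aln An [align_to_reference()] result.
#' @param genes Gene coordinate table ([hml2_genes()] layout).
#' @return A named list of segments; each has `gene`, `sequence`,
#'   `ref_length`, `events` (data.frame `type`, `pos`, `length`),
#'   `absent`, `parts_absent`.
#' @export
project_segments <- function(aln, genes = hml2_genes()) {
  out <- list()
  for (gname in unique(genes$gene)) {
    parts <- genes[genes$gene == gname, , drop = FALSE]
    seq_parts <- character(0)
    events <- list()
    ref_len <- 0L
    offset <- 0L           # segment-coordinate offset across parts
    parts_absent <- 0L
    for (k in seq_len(nrow(parts))) {
      a <- parts$start[k]; b <- parts$end[k]
      ref_len <- ref_len + (b - a + 1L)
      cols <- which(aln$ref_pos >= a & aln$ref_pos <= b & aln$ref_chars != "-")
      if (!length(cols)) { parts_absent <- parts_absent + 1L; next }
      span <- min(cols):max(cols)   # includes insertion columns inside
      pc <- aln$prov_chars[span]
      rc <- aln$ref_chars[span]
      seq_k <- paste(pc[pc != "-"], collapse = "")
      # deletion events: runs of provirus gaps
      isdel <- pc == "-"
      if (any(isdel)) {
        r <- rle(isdel)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(r$values)) {
          # position in segment coordinates: provirus bases emitted
          # before the run, within this gene
          pos_seg <- offset + sum(pc[seq_len(starts[j] - 1L)] != "-") + 1L
          events[[length(events) + 1L]] <-
            data.frame(type = "deletion", pos = pos_seg,
                       length = r$lengths[j], stringsAsFactors = FALSE)
        }
      }
      isins <- rc == "-"
      if (any(isins)) {
        r <- rle(isins)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (j in which(r$values)) {
          pos_seg <- offset + sum(pc[seq_len(starts[j] - 1L)] != "-") + 1L
          events[[length(events) + 1L]] <-
            data.frame(type = "insertion", pos = pos_seg,
                       length = r$lengths[j], stringsAsFactors = FALSE)
        }
      }
      # a part missing its edges relative to the reference interval
      got_ref <- sum(rc != "-")
      if (got_ref < (b - a + 1L)) {
        events[[length(events) + 1L]] <-
          data.frame(type = "deletion", pos = offset + 1L,
                     length = (b - a + 1L) - got_ref,
                     stringsAsFactors = FALSE)
      }
      seq_parts <- c(seq_parts, seq_k)
      offset <- offset + nchar(seq_k)
    }
    sequence <- paste(seq_parts, collapse = "")
    out[[gname]] <- list(
      gene = gname, sequence = sequence, ref_length = ref_len,
      events = if (length(events)) do.call(rbind, events)
               else data.frame(type = character(), pos = integer(),
                               length = integer(), stringsAsFactors = FALSE),
      absent = !nzchar(sequence),
      parts_absent = parts_absent)
  }
  out
}

#' Scan one projected gene segment for ORF-disrupting lesions
#'
#' Context-free verdict: a segment is intact when its translation in
#' the reference reading frame has no premature stop codon, it carries
#' no frameshifting indel (length not a multiple of 3), no missing
#' subinterval, and no in-frame indel longer than `in_frame_tol` of
#' the segment.
#'
#' @param segment One element of [project_segments()].
#' @param in_frame_tol In-frame indels removing/adding more than this
#'   fraction of the reference segment length break intactness.
#' @return An object of class `orf_verdict`: list with `gene`,
#'   `intact`, `absent`, `lesions` (character descriptions),
#'   `premature_stop_codon` (index or NA).
#' @export
scan_orf <- function(segment, in_frame_tol = 0.05) {
  lesions <- character(0)
  if (segment$absent || nchar(segment$sequence) < 3L) {
    return(structure(list(gene = segment$gene, intact = FALSE,
                          absent = TRUE, lesions = "segment absent",
                          premature_stop_codon = NA_integer_),
                     class = "orf_verdict"))
  }
  if (segment$parts_absent > 0L)
    lesions <- c(lesions, sprintf("%d spliced part(s) missing",
                                  segment$parts_absent))
  ev <- segment$events
  if (nrow(ev)) {
    shift <- ev$length %% 3L != 0L
    for (j in which(shift))
      lesions <- c(lesions, sprintf("frameshifting %s of %d nt at segment nt %d",
                                    ev$type[j], ev$length[j], ev$pos[j]))
    big <- !shift & ev$length > in_frame_tol * segment$ref_length
    for (j in which(big))
      lesions <- c(lesions, sprintf("large in-frame %s of %d nt at segment nt %d",
                                    ev$type[j], ev$length[j], ev$pos[j]))
  }
  aa <- translate_dna(segment$sequence)
  stops <- unlist(gregexpr("*", aa, fixed = TRUE))
  n_codons <- nchar(aa)
  premature <- NA_integer_
  if (stops[1] != -1L) {
    # a stop at the segment's final complete codon is the terminator;
    # anything earlier is premature
    early <- stops[stops < n_codons]
    if (length(early)) {
      premature <- early[1]
      lesions <- c(lesions, sprintf("premature stop at codon %d", premature))
    }
  }
  structure(list(gene = segment$gene, intact = length(lesions) == 0L,
                 absent = FALSE, lesions = lesions,
                 premature_stop_codon = premature),
            class = "orf_verdict")
}

#' Provirus-level ORF report with context rules
#'
#' Applies the polyprotein-context and provirus-type rules to the six
#' context-free verdicts: `pro` requires an intact `gag` upstream and
#' `pol` requires intact `gag` and `pro` (a deleterious N-terminal
#' mutation ablates downstream translation of the GagProPol
#' polyprotein); type 1 proviruses cannot express `env` or `rec` (they
#' express `np9` instead); for type 2, `np9` is not applicable.
#'
#' @param verdicts Named list of [scan_orf()] verdicts for the six
#'   genes.
#' @param provirus_type 1 or 2.
#' @param locus_id Optional label.
#' @return A data.frame (one row per gene): `gene`, `orf_intact`
#'   (sequence-level), `context_ok`, `expressible`, `intact`
#'   (final call), `lesions`, `note`.
#' @export
classify_provirus <- function(verdicts, provirus_type = 2L,
                              locus_id = NA_character_) {
  need <- c("gag", "pro", "pol", "env", "rec", "np9")
  miss <- setdiff(need, names(verdicts))
  if (length(miss))
    stop("verdict(s) missing for gene(s): ", paste(miss, collapse = ", "))
  ok <- vapply(need, function(g) isTRUE(verdicts[[g]]$intact), TRUE)
  ctx <- c(gag = TRUE,
           pro = unname(ok["gag"]),
           pol = unname(ok["gag"] && ok["pro"]),
           env = TRUE, rec = TRUE, np9 = TRUE)
  expressible <- stats::setNames(rep(TRUE, 6L), need)
  note <- stats::setNames(rep("", 6L), need)
  if (provirus_type == 1L) {
    expressible[c("env", "rec")] <- FALSE
    note[c("env", "rec")] <- "type 1: not expressible (pol-env deletion)"
    note["np9"] <- "type 1: np9 transcript"
  } else {
    expressible["np9"] <- FALSE
    note["np9"] <- "type 2: not applicable"
  }
  if (!ctx["pro"]) note["pro"] <- "gag disrupted upstream (GagProPol context)"
  if (!ctx["pol"]) note["pol"] <- "gag/pro disrupted upstream (GagProPol context)"
  data.frame(
    locus_id = locus_id, gene = need,
    orf_intact = unname(ok), context_ok = unname(ctx[need]),
    expressible = unname(expressible),
    intact = unname(ok & ctx[need] & expressible),
    lesions = vapply(need, function(g)
      paste(verdicts[[g]]$lesions, collapse = "; "), ""),
    note = unname(note),
    stringsAsFactors = FALSE)
}

#' Full ORF report for a set of proviruses
#'
#' Aligns each provirus to the reference, projects the gene intervals,
#' scans each segment and applies the provirus-level rules.
#'
#' @param sequences Named list/vector of provirus DNA strings in
#'   template orientation (e.g. [locus_sequence()]).
#' @param types Named integer vector of provirus types (default 2).
#' @param template Reference [hml2_template()].
#' @param in_frame_tol Passed to [scan_orf()].
#' @return A data.frame of per-gene calls across loci
#'   ([classify_provirus()] layout).
#' @export
orf_report <- function(sequences, types = NULL,
                       template = hml2_template(), in_frame_tol = 0.05) {
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by locus_id")
  out <- lapply(ids, function(id) {
    aln <- align_to_reference(sequences[[id]], template$sequence)
    segs <- project_segments(aln, template$genes)
    verd <- lapply(segs, scan_orf, in_frame_tol = in_frame_tol)
    tp <- if (!is.null(types) && id %in% names(types)) types[[id]] else 2L
    classify_provirus(verd, provirus_type = tp, locus_id = id)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
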