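# Synthetic genome construction: plants annotated proviral loci (with
# LTR subtypes, type 1/2 structure, solo LTRs and controlled lesions)
# into toy chromosomes, recording exact ground truth for every base.

#' Describe a provirus to plant
#'
#' @param locus_id Cytoband-style identifier (e.g. `"3q12.3"`).
#' @param chrom Chromosome name.
#' @param start 1-based genomic start of the planted locus.
#' @param strand `"+"` or `"-"`.
#' @param ltr_subtype One of `LTR5A`, `LTR5B`, `LTR5HS`.
#' @param esa_group Earliest-shared-ancestor age group, one of
#'   `r paste(ESA_GROUPS, collapse = ", ")`.
#' @param type Provirus type, 1 (carries the 292-nt pol-env border
#'   deletion) or 2 (full length). For type 1 the deletion lesion is
#'   added automatically when not supplied.
#' @param lesions List of [lesion()] objects in template coordinates.
#' @param has_5ltr If `FALSE` the 5' LTR (template 1-968) is absent
#'   from the planted locus.
#' @param mechanism Transcript unit used by the read simulator:
#'   `"ltr_driven"` (U3-R border of the driving LTR to the 3' R-U5
#'   border) or `"read_through"` (a window starting upstream of the
#'   provirus and running through it).
#' @param upstream_driver_offset If set, a solo LTR (subtype LTR5HS) is
#'   planted so that its 3' end lies exactly this many bp upstream of
#'   the provirus 5' boundary, and LTR-driven transcription initiates
#'   at that solo LTR.
#' @return An object of class `provirus_spec`.
#' @examples
#' provirus_spec("3q12.3", "chr3", 5000, ltr_subtype = "LTR5HS",
#'               esa_group = "Gorilla")
#' @export
provirus_spec <- function(locus_id, chrom, start, strand = "+",
                          ltr_subtype = "LTR5HS", esa_group = "Gorilla",
                          type = 2L, lesions = list(), has_5ltr = TRUE,
                          mechanism = c("ltr_driven", "read_through"),
                          upstream_driver_offset = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!ltr_subtype %in% LTR_SUBTYPES)
    stop("ltr_subtype must be one of ", paste(LTR_SUBTYPES, collapse = ", "))
  if (!esa_group %in% ESA_GROUPS)
    stop("esa_group must be one of ", paste(ESA_GROUPS, collapse = ", "))
  type <- as.integer(type)
  if (!type %in% c(1L, 2L)) stop("type must be 1 or 2")
  if (!all(vapply(lesions, inherits, TRUE, "lesion")))
    stop("lesions must be a list of lesion() objects")
  if (type == 1L && !has_type1_deletion(lesions))
    lesions <- c(lesions, list(type1_deletion()))
  structure(
    list(locus_id = locus_id, chrom = chrom, start = as.integer(start),
         strand = strand, ltr_subtype = ltr_subtype, esa_group = esa_group,
         type = type, lesions = lesions, has_5ltr = isTRUE(has_5ltr),
         mechanism = mechanism,
         upstream_driver_offset =
           if (is.null(upstream_driver_offset)) NULL
           else as.integer(upstream_driver_offset)),
    class = c("provirus_spec", "locus_spec")
  )
}

type1_deletion <- function() {
  lesion("deletion", TYPE1_DELETION_START, TYPE1_DELETION_LENGTH)
}

has_type1_deletion <- function(lesions) {
  any(vapply(lesions, function(l)
    l$kind == "deletion" && identical(l$payload, TYPE1_DELETION_LENGTH), TRUE))
}

#' Convert a type 2 provirus spec to type 1
#'
#' Adds the 292-nt deletion at the template's pol-env border region and
#' flips the type flag. The derived planted sequence is exactly 292 nt
#' shorter than the type 2 one.
#'
#' @param spec A type 2 [provirus_spec()].
#' @param template The [hml2_template()] (must carry pol and env
#'   coordinates).
#' @return The modified `provirus_spec` (type 1).
#' @export
make_type1 <- function(spec, template = hml2_template()) {
  stopifnot(inherits(spec, "provirus_spec"))
  if (spec$type == 1L)
    stop("spec '", spec$locus_id, "' is already type 1")
  g <- template$genes
  if (!all(c("pol", "env") %in% g$gene))
    stop("template lacks pol/env coordinates; cannot place the type 1 deletion")
  spec$type <- 1L
  spec$lesions <- c(spec$lesions, list(type1_deletion()))
  spec
}

#' Describe a standalone solo LTR
#'
#' @inheritParams provirus_spec
#' @return An object of class `solo_ltr_spec`.
#' @export
solo_ltr_spec <- function(locus_id, chrom, start, strand = "+",
                          ltr_subtype = "LTR5HS", esa_group = "Gorilla") {
  if (!ltr_subtype %in% LTR_SUBTYPES)
    stop("ltr_subtype must be one of ", paste(LTR_SUBTYPES, collapse = ", "))
  structure(
    list(locus_id = locus_id, chrom = chrom, start = as.integer(start),
         strand = strand, ltr_subtype = ltr_subtype, esa_group = esa_group),
    class = c("solo_ltr_spec", "locus_spec")
  )
}

#' Describe a host gene interval
#'
#' Host genes are annotated intervals of the background sequence; they
#' provide unique-mapping transcription units and read-through drivers.
#'
#' @inheritParams provirus_spec
#' @param length Gene length in nt.
#' @return An object of class `host_gene_spec`.
#' @export
host_gene_spec <- function(locus_id, chrom, start, length = 3000L,
                           strand = "+") {
  structure(
    list(locus_id = locus_id, chrom = chrom, start = as.integer(start),
         length = as.integer(length), strand = strand),
    class = c("host_gene_spec", "locus_spec")
  )
}

# per-LTR-subtype substitutions (LTR-local), applied identically to
# both LTRs. The template LTR *is* the LTR5HS baseline (its words are
# already planted), so LTR5HS is a no-op; LTR5A and LTR5B substitute
# the diagnostic sites and replace the subtype word slots.
apply_subtype_ltr <- function(ltr_chars, subtype) {
  if (subtype == "LTR5HS") return(ltr_chars)
  sites <- .subtype_sites()$positions
  rot <- if (subtype == "LTR5A") c(A = "C", C = "G", G = "T", T = "A")
         else c(A = "G", C = "T", G = "A", T = "C")
  ltr_chars[sites] <- unname(rot[ltr_chars[sites]])
  ms <- .motif_sites()
  own <- ms[ms$subtype == subtype, , drop = FALSE]
  for (i in seq_len(nrow(own))) {
    p <- own$ltr_pos[i]
    w <- strsplit(own$word[i], "")[[1]]
    ltr_chars[p:(p + length(w) - 1L)] <- w
  }
  ltr_chars
}

# spans in which substitutions must not create TA/TG dinucleotides
# (gene intervals plus their 3'-LTR-copy images)
.coding_constrained <- function(pos) {
  (pos <= 88L) | (pos >= 1111L & pos <= 8592L)
}

#' Build a synthetic genome with planted proviral loci
#'
#' Plants each spec'd locus into random-background chromosomes. Every
#' provirus starts from the template, receives its LTR-subtype edits,
#' per-provirus divergence substitutions (mirrored across the two LTRs,
#' plus small independent per-LTR private substitutions), and finally
#' its requested lesions. Divergence substitutions inside gene spans
#' never create stop codons, so ORF truth is controlled entirely by the
#' lesion list.
#'
#' @param specs List of [provirus_spec()], [solo_ltr_spec()] and
#'   [host_gene_spec()] objects. Loci on one chromosome must not
#'   overlap.
#' @param template The provirus [hml2_template()].
#' @param host_gene_count Number of additional host genes auto-placed
#'   downstream of the last locus on each chromosome.
#' @param divergence Expected pairwise divergence between two
#'   same-template proviruses (each provirus receives substitutions at
#'   rate `divergence / 2`).
#' @param ltr_private_divergence Per-LTR private substitution rate
#'   applied independently to the 5' and 3' LTR after mirroring.
#' @param pad Background padding (nt) before the first and after the
#'   last locus on each chromosome.
#' @param seed Integer seed; the build is bit-reproducible.
#' @return An object of class `hml2_genome`: list with `chroms` (named
#'   character vector of chromosome sequences), `annotation` (the locus
#'   table, 1-based inclusive coordinates, classes `provirus`,
#'   `solo_LTR`, `host_gene`), `loci` (internal per-locus truth:
#'   template-orientation sequence and template coordinate map) and
#'   `template`.
#' @examples
#' g <- build_genome(list(
#'   provirus_spec("1q21.3", "chr1", 6000),
#'   provirus_spec("3q12.3", "chr1", 26000)
#' ), seed = 1)
#' g$annotation
#' @export
build_genome <- function(specs, template = hml2_template(),
                         host_gene_count = 0L, divergence = 0.02,
                         ltr_private_divergence = 0.002,
                         pad = 4000L, seed = 1L) {
  if (!length(specs)) stop("no loci specified")
  if (!all(vapply(specs, inherits, TRUE, "locus_spec")))
    stop("specs must be locus_spec objects (provirus_spec / solo_ltr_spec / host_gene_spec)")
  ids <- vapply(specs, `[[`, "", "locus_id")
  if (anyDuplicated(ids))
    stop("duplicate locus_id: ", ids[duplicated(ids)][1])

  with_seed(seed, {
    tpl_chars <- strsplit(template$sequence, "")[[1]]
    loci <- list()
    ann <- list()

    expand <- list()
    for (sp in specs) {
      expand <- c(expand, list(sp))
      if (inherits(sp, "provirus_spec") && !is.null(sp$upstream_driver_offset)) {
        # solo LTR whose 3' end is exactly `offset` bp upstream of the
        # provirus 5' boundary (strand-aware)
        off <- sp$upstream_driver_offset
        solo_id <- paste0(sp$locus_id, "HS")
        if (sp$strand == "+") {
          solo_start <- sp$start - off - LTR_LENGTH + 1L
        } else {
          # placed after the provirus in genomic coordinates
          solo_start <- NA_integer_  # filled once provirus end is known
        }
        expand <- c(expand, list(structure(
          list(locus_id = solo_id, chrom = sp$chrom, start = solo_start,
               strand = sp$strand, ltr_subtype = "LTR5HS",
               esa_group = sp$esa_group, driver_for = sp$locus_id,
               offset = off),
          class = c("solo_ltr_spec", "locus_spec"))))
      }
    }

    for (sp in expand) {
      if (inherits(sp, "provirus_spec")) {
        chars <- tpl_chars
        # subtype edits on the 5' LTR
        ltr <- apply_subtype_ltr(chars[LTR5_REGION[1]:LTR5_REGION[2]],
                                 sp$ltr_subtype)
        chars[LTR5_REGION[1]:LTR5_REGION[2]] <- ltr
        # divergence substitutions over template minus the 3' LTR;
        # 5' LTR hits are mirrored into the 3' LTR below
        sr <- charToRaw(paste(chars, collapse = ""))
        n_sub <- stats::rbinom(1L, LTR3_REGION[1] - 1L, divergence / 2)
        pos <- sample.int(LTR3_REGION[1] - 1L, n_sub)
        sr <- substitute_bases(sr, pos, .coding_constrained(pos))
        # mirror the full 5' LTR (subtype + divergence) into the 3' LTR
        sr[LTR3_REGION[1]:LTR3_REGION[2]] <- sr[LTR5_REGION[1]:LTR5_REGION[2]]
        # independent per-LTR private substitutions
        for (reg in list(LTR5_REGION, LTR3_REGION)) {
          k <- stats::rbinom(1L, LTR_LENGTH, ltr_private_divergence)
          if (k > 0L) {
            p <- sample(seq(reg[1], reg[2]), k)
            sr <- substitute_bases(sr, p, .coding_constrained(p))
          }
        }
        lesions <- sp$lesions
        if (!sp$has_5ltr)
          lesions <- c(list(lesion("deletion", 1L, LTR_LENGTH)), lesions)
        res <- apply_lesions(rawToChar(sr), lesions)
        loci[[sp$locus_id]] <- list(spec = sp, sequence = res$sequence,
                                    map = res$map, tpos = res$tpos)
      } else if (inherits(sp, "solo_ltr_spec")) {
        chars <- tpl_chars[LTR5_REGION[1]:LTR5_REGION[2]]
        chars <- apply_subtype_ltr(chars, sp$ltr_subtype)
        sr <- charToRaw(paste(chars, collapse = ""))
        k <- stats::rbinom(1L, LTR_LENGTH, divergence / 2)
        if (k > 0L)
          sr <- substitute_bases(sr, sample.int(LTR_LENGTH, k),
                                 rep(FALSE, k))
        loci[[sp$locus_id]] <- list(spec = sp, sequence = rawToChar(sr),
                                    map = data.frame(tstart = 1L,
                                                     tend = LTR_LENGTH,
                                                     lstart = 1L),
                                    tpos = seq_len(LTR_LENGTH))
      } else { # host gene: background interval, sequence filled later
        loci[[sp$locus_id]] <- list(spec = sp, sequence = NULL, map = NULL)
      }
    }

    # resolve deferred solo LTR placement on '-' strand proviruses
    for (id in names(loci)) {
      sp <- loci[[id]]$spec
      if (inherits(sp, "solo_ltr_spec") && !is.null(sp$driver_for) &&
          is.na(sp$start)) {
        pv <- loci[[sp$driver_for]]
        pv_end <- pv$spec$start + nchar(pv$sequence) - 1L
        loci[[id]]$spec$start <- pv_end + sp$offset
      }
    }

    # genomic placement and overlap check
    place <- do.call(rbind, lapply(names(loci), function(id) {
      lc <- loci[[id]]; sp <- lc$spec
      len <- if (inherits(sp, "host_gene_spec")) sp$length
             else nchar(lc$sequence)
      data.frame(locus_id = id, chrom = sp$chrom, start = sp$start,
                 end = sp$start + len - 1L, strand = sp$strand,
                 class = if (inherits(sp, "provirus_spec")) "provirus"
                         else if (inherits(sp, "solo_ltr_spec")) "solo_LTR"
                         else "host_gene",
                 stringsAsFactors = FALSE)
    }))
    if (any(place$start < 1L))
      stop("locus extends before position 1: ",
           place$locus_id[place$start < 1L][1])
    for (ch in unique(place$chrom)) {
      p <- place[place$chrom == ch, ]
      p <- p[order(p$start), ]
      if (nrow(p) > 1L) {
        ov <- which(p$start[-1] <= p$end[-nrow(p)])
        if (length(ov))
          stop("overlapping loci on ", ch, ": ", p$locus_id[ov[1]],
               " and ", p$locus_id[ov[1] + 1L])
      }
    }

    # auto-placed host genes
    if (host_gene_count > 0L) {
      for (k in seq_len(host_gene_count)) {
        ch <- unique(place$chrom)[1L]
        at <- max(place$end[place$chrom == ch]) + pad + (k - 1L) * 5000L
        id <- sprintf("HG%02d", k)
        sp <- host_gene_spec(id, ch, at)
        loci[[id]] <- list(spec = sp, sequence = NULL, map = NULL)
        place <- rbind(place, data.frame(
          locus_id = id, chrom = ch, start = at, end = at + sp$length - 1L,
          strand = "+", class = "host_gene", stringsAsFactors = FALSE))
      }
    }

    # assemble chromosomes: random background + planted sequences
    chroms <- character(0)
    for (ch in unique(place$chrom)) {
      p <- place[place$chrom == ch, ]
      clen <- max(p$end) + pad
      cr <- charToRaw(random_dna(clen))
      for (i in seq_len(nrow(p))) {
        lc <- loci[[p$locus_id[i]]]
        if (is.null(lc$sequence)) { # host gene keeps background sequence
          loci[[p$locus_id[i]]]$sequence <-
            rawToChar(cr[p$start[i]:p$end[i]])
          next
        }
        planted <- if (p$strand[i] == "+") lc$sequence else revcomp(lc$sequence)
        cr[p$start[i]:p$end[i]] <- charToRaw(planted)
      }
      chroms[ch] <- rawToChar(cr)
    }

    # annotation table (LTR genomic coordinates included)
    ann <- place
    ann$ltr_subtype <- NA_character_
    ann$esa_group <- NA_character_
    ann$type <- NA_integer_
    ann$mechanism <- NA_character_
    ann$upstream_driver <- NA_character_
    ann$ltr5_start <- NA_integer_; ann$ltr5_end <- NA_integer_
    ann$ltr3_start <- NA_integer_; ann$ltr3_end <- NA_integer_
    for (i in seq_len(nrow(ann))) {
      lc <- loci[[ann$locus_id[i]]]; sp <- lc$spec
      if (ann$class[i] == "provirus") {
        ann$ltr_subtype[i] <- sp$ltr_subtype
        ann$esa_group[i] <- sp$esa_group
        ann$type[i] <- sp$type
        ann$mechanism[i] <- sp$mechanism
        if (!is.null(sp$upstream_driver_offset))
          ann$upstream_driver[i] <- paste0(sp$locus_id, "HS")
        l5 <- map_template_span(lc$map, LTR5_REGION[1], LTR5_REGION[2])
        l3 <- map_template_span(lc$map, LTR3_REGION[1], LTR3_REGION[2])
        glen <- nchar(lc$sequence)
        to_g <- function(lstart, width) {
          if (is.na(lstart)) return(c(NA_integer_, NA_integer_))
          if (ann$strand[i] == "+")
            c(ann$start[i] + lstart - 1L, ann$start[i] + lstart + width - 2L)
          else
            c(ann$end[i] - (lstart + width - 2L), ann$end[i] - (lstart - 1L))
        }
        g5 <- to_g(l5, LTR_LENGTH); g3 <- to_g(l3, LTR_LENGTH)
        ann$ltr5_start[i] <- g5[1]; ann$ltr5_end[i] <- g5[2]
        ann$ltr3_start[i] <- g3[1]; ann$ltr3_end[i] <- g3[2]
      } else if (ann$class[i] == "solo_LTR") {
        ann$ltr_subtype[i] <- sp$ltr_subtype
        ann$esa_group[i] <- sp$esa_group %||% NA_character_
      }
    }
    ann$length <- ann$end - ann$start + 1L
    ann <- ann[order(ann$chrom, ann$start), ]
    rownames(ann) <- NULL

    structure(list(chroms = chroms, annotation = ann, loci = loci,
                   template = template, divergence = divergence,
                   seed = seed),
              class = "hml2_genome")
  })
}

#' @export
print.hml2_genome <- function(x, ...) {
  cat("Synthetic HML-2 genome:", length(x$chroms), "chromosome(s),",
      sum(x$annotation$class == "provirus"), "proviruses,",
      sum(x$annotation$class == "solo_LTR"), "solo LTRs,",
      sum(x$annotation$class == "host_gene"), "host genes\n")
  invisible(x)
}

#' Extract a planted locus sequence in template orientation
#'
#' @param genome An `hml2_genome`.
#' @param locus_id Locus identifier.
#' @return DNA string (reverse-complemented for '-' strand loci, i.e.
#'   always in template orientation).
#' @export
locus_sequence <- function(genome, locus_id) {
  lc <- genome$loci[[locus_id]]
  if (is.null(lc)) stop("unknown locus: ", locus_id)
  lc$sequence
}
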