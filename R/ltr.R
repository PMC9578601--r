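# LTR extraction, p-distance and neighbor-joining phylogeny.

#' Extract LTR sequences from proviruses and solo LTRs
#'
#' 5' LTRs are the projection of reference 1-968 and 3' LTRs of
#' 8505-9472 through a global alignment of each provirus to the
#' reference; solo LTRs contribute their full sequence. A provirus
#' lacking its 5' LTR yields a single 3' record flagged `"*"`; a
#' provirus with neither LTR is excluded with a warning.
#'
#' @param genome An `hml2_genome`, or a named list of provirus DNA
#'   strings (template orientation).
#' @param annotation Required when `genome` is a plain list: the locus
#'   annotation table.
#' @param template Reference [hml2_template()].
#' @param min_length,max_length Sanity band on extracted LTR lengths.
#' @return A data.frame: `ltr_id`, `locus_id`, `kind`
#'   (`5p`/`3p`/`solo`), `subtype`, `flag`, `sequence`, `length`.
#' @export
extract_ltrs <- function(genome, annotation = NULL,
                         template = hml2_template(),
                         min_length = 600L, max_length = 1100L) {
  if (inherits(genome, "hml2_genome")) {
    annotation <- genome$annotation
    seqs <- lapply(genome$annotation$locus_id[
      genome$annotation$class == "provirus"],
      function(id) genome$loci[[id]]$sequence)
    names(seqs) <- genome$annotation$locus_id[
      genome$annotation$class == "provirus"]
    solo_ids <- annotation$locus_id[annotation$class == "solo_LTR"]
    solos <- lapply(solo_ids, function(id) genome$loci[[id]]$sequence)
    names(solos) <- solo_ids
  } else {
    if (is.null(annotation)) stop("annotation required for plain sequences")
    seqs <- genome
    solos <- list()
  }
  rows <- list()
  for (id in names(seqs)) {
    aln <- align_to_reference(seqs[[id]], template$sequence)
    segs <- project_segments(aln, data.frame(
      gene = c("ltr5", "ltr3"), part = c(1L, 1L),
      start = c(LTR5_REGION[1], LTR3_REGION[1]),
      end = c(LTR5_REGION[2], LTR3_REGION[2])))
    sub <- annotation$ltr_subtype[match(id, annotation$locus_id)]
    has5 <- !segs$ltr5$absent &&
      nchar(segs$ltr5$sequence) >= min_length
    has3 <- !segs$ltr3$absent &&
      nchar(segs$ltr3$sequence) >= min_length
    if (!has5 && !has3) {
      warning("provirus ", id, " has no usable LTR; excluded")
      next
    }
    if (has5)
      rows[[length(rows) + 1L]] <- data.frame(
        ltr_id = paste0(id, "_5p"), locus_id = id, kind = "5p",
        subtype = sub, flag = "", sequence = segs$ltr5$sequence,
        stringsAsFactors = FALSE)
    if (has3)
      rows[[length(rows) + 1L]] <- data.frame(
        ltr_id = paste0(id, "_3p"), locus_id = id, kind = "3p",
        subtype = sub, flag = if (has5) "" else "*",
        sequence = segs$ltr3$sequence, stringsAsFactors = FALSE)
  }
  for (id in names(solos)) {
    sub <- annotation$ltr_subtype[match(id, annotation$locus_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      ltr_id = paste0(id, "_solo"), locus_id = id, kind = "solo",
      subtype = sub, flag = "*", sequence = solos[[id]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$length <- nchar(out$sequence)
  bad <- out$length < min_length | out$length > max_length
  if (any(bad)) {
    warning("LTR(s) outside the sanity length band excluded: ",
            paste(out$ltr_id[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Reference-anchored LTR alignment matrix
#'
#' Aligns each LTR to the reference 968-nt LTR and projects it onto
#' the reference columns (insertions relative to the reference are
#' dropped; deletions appear as `-`). The resulting character matrix
#' feeds [p_distance()] and column-bootstrap resampling.
#'
#' @param ltrs An [extract_ltrs()] table or a named character vector.
#' @param template Reference template (its 5' LTR is the anchor).
#' @return Character matrix (LTRs x 968 reference columns).
#' @export
ltr_msa <- function(ltrs, template = hml2_template()) {
  seqs <- if (is.data.frame(ltrs))
    stats::setNames(ltrs$sequence, ltrs$ltr_id) else ltrs
  ref <- substr(template$sequence, LTR5_REGION[1], LTR5_REGION[2])
  n <- length(seqs)
  m <- matrix("-", n, nchar(ref),
              dimnames = list(names(seqs), NULL))
  for (i in seq_len(n)) {
    aln <- align_to_reference(seqs[[i]], ref)
    keep <- aln$ref_pos > 0L
    m[i, aln$ref_pos[keep]] <- aln$prov_chars[keep]
  }
  m
}

#' Pairwise p-distance
#'
#' Proportion of differing sites between two aligned sequences, gap
#' positions excluded pairwise.
#'
#' @param msa Character alignment matrix (sequences x columns, gaps as
#'   `-`), or a character vector of equal-length ungapped sequences.
#' @return Symmetric numeric matrix with zero diagonal; `NA` (with a
#'   warning) when a pair shares no comparable position.
#' @export
p_distance <- function(msa) {
  if (!is.matrix(msa)) {
    if (length(unique(nchar(msa))) != 1L)
      stop("sequences must be pre-aligned (equal length)")
    nm <- names(msa)
    msa <- do.call(rbind, strsplit(msa, ""))
    rownames(msa) <- nm
  }
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  gap <- msa == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) {
      warning("no comparable positions between ", rownames(msa)[i],
              " and ", rownames(msa)[j])
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- mean(msa[i, ok] != msa[j, ok])
    }
  }
  d
}

#' Neighbor-joining LTR tree with bootstrap supports
#'
#' Saitou-Nei neighbor joining on the p-distance matrix of a
#' reference-anchored LTR alignment; negative branch lengths are
#' clamped to zero (count recorded in attribute `n_clamped`).
#' Bootstrap resamples alignment columns, recomputes distances and
#' trees, and reports each internal clade's resample frequency as a
#' node label in [0, 1].
#'
#' @param msa [ltr_msa()] matrix (>= 3 rows).
#' @param bootstrap Number of bootstrap replicates (default 500).
#' @param seed Integer seed for resampling.
#' @return An `ape::phylo` tree; `node.label` holds bootstrap support
#'   proportions.
#' @export
nj_ltr_tree <- function(msa, bootstrap = 500L, seed = 1L) {
  if (nrow(msa) < 3L) stop("need >= 3 taxa")
  D <- p_distance(msa)
  if (anyNA(D)) {
    bad <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop("NA distance between ", rownames(D)[bad[1]], " and ",
         colnames(D)[bad[2]])
  }
  tree <- nj_tree(D)
  if (bootstrap > 0L) {
    boots <- with_seed(seed, {
      lapply(seq_len(bootstrap), function(b) {
        cols <- sample.int(ncol(msa), replace = TRUE)
        Db <- suppressWarnings(p_distance(msa[, cols, drop = FALSE]))
        Db[is.na(Db)] <- max(Db, na.rm = TRUE)
        nj_tree(Db)
      })
    })
    pc <- ape::prop.clades(tree, boots, rooted = FALSE)
    pc[is.na(pc)] <- 0L
    tree$node.label <- pc / bootstrap
  }
  tree
}

#' Neighbor joining on a distance matrix
#'
#' Thin wrapper around the Saitou-Nei algorithm (`ape::nj`) that
#' validates the matrix and clamps negative branch lengths to zero.
#'
#' @param D Symmetric non-negative distance matrix (>= 3 taxa).
#' @return An `ape::phylo` tree with attribute `n_clamped`.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need >= 3 taxa")
  if (any(D < 0)) stop("distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(D))
  ncl <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "n_clamped") <- ncl
  tree
}

#' Are two taxa sister leaves on a tree?
#'
#' @param tree An `ape::phylo`.
#' @param a,b Tip labels.
#' @return TRUE when the two tips form a cherry.
#' @export
is_sister_pair <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("tip not found")
  pa <- tree$edge[tree$edge[, 2] == ia, 1]
  pb <- tree$edge[tree$edge[, 2] == ib, 1]
  pa == pb
}
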