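# Clustering of LTRs on the binary motif-presence matrix: Ward-type
# hierarchical agglomeration on Euclidean distances of binary rows,
# with bootstrap (over motif columns) clade supports and per-clade
# defining motifs.

# leaf-label sets of every internal node of an hclust tree
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    mem <- unlist(lapply(kids, function(k)
      if (k < 0) hc$labels[-k] else sets[[k]]))
    sets[[i]] <- sort(mem)
  }
  sets
}

#' Cluster LTRs by transcription-factor motif presence
#'
#' Rows are sorted lexicographically before clustering, so the result
#' is invariant to input order. Bootstrap resamples motif columns
#' (with replacement), re-clusters, and reports each internal clade's
#' resample frequency. Defining motifs of a clade are motifs present
#' in all of its members and absent from every member of its sibling
#' clade (or the reverse).
#'
#' @param m Binary LTR x motif matrix ([motif_presence()]).
#' @param bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param method Agglomeration method (default `ward.D2`).
#' @return An object of class `motif_clustering`: list with `matrix`,
#'   `hclust`, `clades` (data.frame `node`, `size`, `members`,
#'   `support`), `defining` (data.frame: clade members, sibling,
#'   defining motifs).
#' @export
motif_cluster <- function(m, bootstrap = 1000L, seed = 1L,
                          method = "ward.D2") {
  if (nrow(m) < 2L || ncol(m) < 1L)
    stop("need >= 2 LTRs and >= 1 motif")
  if (all(apply(m, 2L, function(x) length(unique(x)) == 1L)))
    stop("no variation to cluster (constant motif matrix)")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = method)
  clades <- hclust_clades(hc)
  keys <- vapply(clades, paste, "", collapse = "\r")

  support <- rep(0L, length(clades))
  if (bootstrap > 0L) {
    with_seed(seed, {
      for (b in seq_len(bootstrap)) {
        cols <- sample.int(ncol(m), replace = TRUE)
        hb <- stats::hclust(stats::dist(m[, cols, drop = FALSE]),
                            method = method)
        bk <- vapply(hclust_clades(hb), paste, "", collapse = "\r")
        support <- support + (keys %in% bk)
      }
    })
    support <- support / bootstrap
  }

  # defining motifs: present in all members of a clade (internal node
  # or single leaf) and absent from every member of its sibling
  kids_of <- hc$merge
  members_of <- function(k)
    if (k < 0) hc$labels[-k] else clades[[k]]
  def_rows <- list()
  for (i in seq_len(nrow(kids_of))) {
    a <- members_of(kids_of[i, 1]); b <- members_of(kids_of[i, 2])
    for (side in 1:2) {
      mem <- if (side == 1) a else b
      sib <- if (side == 1) b else a
      inall <- colSums(m[mem, , drop = FALSE]) == length(mem)
      outall <- colSums(m[sib, , drop = FALSE]) == 0L
      hit <- colnames(m)[inall & outall]
      if (length(hit))
        def_rows[[length(def_rows) + 1L]] <- data.frame(
          members = paste(sort(mem), collapse = ","),
          sibling = paste(sort(sib), collapse = ","),
          n_defining = length(hit),
          motifs = paste(hit, collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  defining <- if (length(def_rows))
    do.call(rbind, def_rows)
  else data.frame(members = character(), sibling = character(),
                  n_defining = integer(), motifs = character(),
                  stringsAsFactors = FALSE)

  clade_df <- data.frame(
    node = seq_along(clades),
    size = lengths(clades),
    members = vapply(clades, paste, "", collapse = ","),
    support = support,
    stringsAsFactors = FALSE)
  structure(list(matrix = m, hclust = hc, clades = clade_df,
                 defining = defining, bootstrap = bootstrap),
            class = "motif_clustering")
}

#' @export
print.motif_clustering <- function(x, ...) {
  cat("motif_clustering:", nrow(x$matrix), "LTRs x", ncol(x$matrix),
      "motifs;", nrow(x$clades), "internal nodes;",
      x$bootstrap, "bootstrap replicates\n")
  top <- x$clades[x$clades$size < nrow(x$matrix), ]
  top <- utils::head(top[order(-top$support), ], 5L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  clade {%s}: support %.2f\n", top$members[i],
                top$support[i]))
  invisible(x)
}
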