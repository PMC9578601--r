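# Lesions: controlled mutations planted into a provirus built from the
# template. A lesion is described in template coordinates (1-based
# inclusive) and applied after the per-provirus divergence
# substitutions, so the truth of what was planted is always known.

#' Construct a lesion
#'
#' @param kind One of `"substitution"`, `"insertion"`, `"deletion"`,
#'   `"duplication"`.
#' @param position Template nucleotide position (1-based). For a
#'   substitution, the position replaced; for an insertion, the
#'   position after which the payload is inserted; for a deletion or
#'   duplication, the first position of the affected span.
#' @param payload For substitution/insertion: the replacement/inserted
#'   DNA string. For deletion/duplication: the span length (>= 1).
#' @return An object of class `lesion`.
#' @examples
#' lesion("deletion", 6690, 292)
#' lesion("insertion", 1500, "G")
#' @export
lesion <- function(kind = c("substitution", "insertion", "deletion", "duplication"),
                   position, payload) {
  kind <- match.arg(kind)
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("lesion position must be a positive integer")
  if (kind %in% c("deletion", "duplication")) {
    payload <- as.integer(payload)
    if (is.na(payload) || payload < 1L)
      stop(kind, " length must be >= 1")
  } else {
    payload <- toupper(as.character(payload))
    assert_dna(payload, paste(kind, "payload"))
    if (nchar(payload) < 1L) stop(kind, " payload must be non-empty")
  }
  structure(list(kind = kind, position = position, payload = payload),
            class = "lesion")
}

lesion_span <- function(l) {
  switch(l$kind,
         substitution = c(l$position, l$position + nchar(l$payload) - 1L),
         insertion    = c(l$position, l$position),
         deletion     = c(l$position, l$position + l$payload - 1L),
         duplication  = c(l$position, l$position + l$payload - 1L))
}

#' Apply lesions to a template-derived sequence
#'
#' Applies substitutions first, then indel-type lesions in descending
#' template position, and tracks which template position each emitted
#' base derives from (inserted/duplicated bases map to `NA`).
#'
#' @param sequence DNA string in template coordinates.
#' @param lesions List of [lesion()] objects.
#' @return A list with `sequence` (the mutated string), `tpos` (integer
#'   vector, template position of each base or `NA`), and `map` (a
#'   data.frame of contiguous template segments with columns `tstart`,
#'   `tend`, `lstart`).
#' @export
apply_lesions <- function(sequence, lesions = list()) {
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  tpos <- seq_len(L)
  for (l in lesions) {
    sp <- lesion_span(l)
    if (sp[2] > L || sp[1] < 1L)
      stop("lesion (", l$kind, " at ", l$position,
           ") lies outside the template (1-", L, ")")
  }
  subs <- Filter(function(l) l$kind == "substitution", lesions)
  indels <- Filter(function(l) l$kind != "substitution", lesions)
  for (l in subs) {
    idx <- l$position:(l$position + nchar(l$payload) - 1L)
    chars[idx] <- strsplit(l$payload, "")[[1]]
  }
  ord <- order(vapply(indels, function(l) l$position, 1L), decreasing = TRUE)
  for (l in indels[ord]) {
    at <- match(l$position, tpos)
    if (is.na(at))
      stop("lesion position ", l$position,
           " no longer exists (removed by an earlier lesion)")
    if (l$kind == "deletion") {
      drop <- which(tpos >= l$position & tpos <= l$position + l$payload - 1L)
      chars <- chars[-drop]; tpos <- tpos[-drop]
    } else if (l$kind == "insertion") {
      ins <- strsplit(l$payload, "")[[1]]
      chars <- append(chars, ins, after = at)
      tpos  <- append(tpos, rep(NA_integer_, length(ins)), after = at)
    } else { # duplication: a copy of the span inserted after it
      span <- which(tpos >= l$position & tpos <= l$position + l$payload - 1L)
      ins <- chars[span]
      last <- max(span)
      chars <- append(chars, ins, after = last)
      tpos  <- append(tpos, rep(NA_integer_, length(ins)), after = last)
    }
  }
  list(sequence = paste(chars, collapse = ""),
       tpos = tpos,
       map = segments_from_tpos(tpos))
}

# contiguous template-derived segments of a tpos vector
segments_from_tpos <- function(tpos) {
  lp <- seq_along(tpos)
  keep <- !is.na(tpos)
  if (!any(keep))
    return(data.frame(tstart = integer(), tend = integer(), lstart = integer()))
  t <- tpos[keep]; l <- lp[keep]
  brk <- c(TRUE, diff(t) != 1L | diff(l) != 1L)
  grp <- cumsum(brk)
  data.frame(
    tstart = tapply(t, grp, min),
    tend   = tapply(t, grp, max),
    lstart = tapply(l, grp, function(i) i[1]),
    row.names = NULL
  )
}

# Map a template span [t1, t2] to local coordinates through a segment
# map; returns NA when the span is absent or not contiguous.
map_template_span <- function(map, t1, t2) {
  hit <- which(map$tstart <= t1 & map$tend >= t2)
  if (length(hit) != 1L) return(NA_integer_)
  map$lstart[hit] + (t1 - map$tstart[hit])
}
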