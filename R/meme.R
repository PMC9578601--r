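# MEME minimal-format motif files (the de facto PWM interchange) and a
# simple TSV matrix dialect.

#' Read motifs from a MEME minimal-format file
#'
#' Supports the minimal format: version line, optional ALPHABET and
#' background lines, then `MOTIF id [name]` blocks with a
#' `letter-probability matrix:` header and one row of 4 probabilities
#' per motif position.
#'
#' @param path File path.
#' @return Named list of [pwm()] objects; attribute `background`
#'   carries the file's background frequencies when present.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME file (missing 'MEME version' line): ", path)
  bg <- NULL
  bgl <- which(startsWith(lines, "Background letter frequencies"))
  if (length(bgl)) {
    toks <- strsplit(lines[bgl[1] + 1L], "\\s+")[[1]]
    freq <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(freq) <- toks[seq(1, length(toks), by = 2)]
    bg <- unname(freq[DNA_BASES])
  }
  starts <- which(startsWith(lines, "MOTIF"))
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    toks <- strsplit(lines[i], "\\s+")[[1]]
    id <- toks[2]; name <- if (length(toks) >= 3L) toks[3] else id
    j <- i + 1L
    while (j <= length(lines) &&
           !startsWith(lines[j], "letter-probability matrix"))
      j <- j + 1L
    if (j > length(lines))
      stop("motif ", id, ": missing letter-probability matrix header")
    w <- suppressWarnings(as.integer(sub(".*w=\\s*([0-9]+).*", "\\1",
                                         lines[j])))
    ns <- suppressWarnings(as.integer(sub(".*nsites=\\s*([0-9]+).*", "\\1",
                                          lines[j])))
    if (is.na(ns)) ns <- 20L
    rows <- lines[(j + 1L):(j + w)]
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    if (is.na(w) || nrow(mat) != w || ncol(mat) != 4L)
      stop("motif ", id, ": malformed probability matrix")
    mat <- mat / rowSums(mat)       # guard against rounded rows
    out[[id]] <- pwm(id, mat, name = name, nsites = ns)
  }
  attr(out, "background") <- bg
  out
}

#' Write motifs to a MEME minimal-format file
#'
#' @param pwms Named list of [pwm()] objects.
#' @param path Output path.
#' @param bg Background frequencies for the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, bg = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s %s", p$id, p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(p$mat), p$nsites), con)
    writeLines(apply(p$mat, 1L, function(r)
      sprintf("%.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}
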