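# Minimal SAM text I/O. The pipeline works at desk scale with
# uncompressed SAM (header, the 11 mandatory fields, and the AS
# alignment-score tag); records are kept in a plain data.frame.

SAM_FLAG_REVERSE <- 16L
SAM_FLAG_SECONDARY <- 256L

#' Write alignments to a SAM file
#'
#' @param records data.frame with columns `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, `seq`, `as` (alignment score).
#' @param chrom_lengths Named integer vector for the `@SQ` header.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tAS:i:%d",
                  records$qname, as.integer(records$flag), records$rname,
                  as.integer(records$pos), as.integer(records$mapq),
                  records$cigar, records$seq, as.integer(records$as))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file
#'
#' Parses header and records; requires a header and the `AS` tag on
#' every record.
#'
#' @param path SAM file path.
#' @return A list with `records` (data.frame as in [write_sam()], plus
#'   `read_length`) and `chrom_lengths`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  if (!any(is_hdr))
    stop("SAM file has no header (missing @HD/@SQ lines): ", path)
  hdr <- lines[is_hdr]
  sq <- hdr[startsWith(hdr, "@SQ")]
  chrom_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    chrom_lengths <- stats::setNames(ln, sn)
  }
  body <- lines[!is_hdr]
  if (!length(body)) {
    return(list(records = data.frame(qname = character(), flag = integer(),
                                     rname = character(), pos = integer(),
                                     mapq = integer(), cigar = character(),
                                     seq = character(), as = integer(),
                                     read_length = integer()),
                chrom_lengths = chrom_lengths))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM record (fewer than 11 fields) at line ",
         which(!is_hdr)[which(nf < 11L)[1]])
  get <- function(i) vapply(f, `[[`, "", i)
  opt <- vapply(f, function(x)
    paste(x[-seq_len(11L)], collapse = "\t"), "")
  as_m <- regmatches(opt, regexpr("AS:i:-?[0-9]+", opt))
  has_as <- grepl("AS:i:", opt, fixed = TRUE)
  if (!all(has_as))
    stop("SAM record missing the AS tag (alignment score) at line ",
         which(!is_hdr)[which(!has_as)[1]])
  records <- data.frame(
    qname = get(1L), flag = as.integer(get(2L)), rname = get(3L),
    pos = as.integer(get(4L)), mapq = as.integer(get(5L)),
    cigar = get(6L), seq = get(10L),
    as = as.integer(sub("AS:i:", "", as_m, fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  records$read_length <- nchar(records$seq)
  list(records = records, chrom_lengths = chrom_lengths)
}
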