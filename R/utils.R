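# Small internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library functions do not perturb user-level
#' random streams.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a child seed from a parent seed
#'
#' Deterministically maps (seed, stream index) to a 31-bit integer so
#' every stochastic stage of a run receives its own reproducible seed.
#' @keywords internal
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")
.base_raw <- charToRaw("ACGT")

dna_to_raw <- function(x) charToRaw(x)
raw_to_dna <- function(r) rawToChar(r)

#' @keywords internal
#' @noRd
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# vectorised reverse complement on a raw vector
revcomp_raw <- function(r) {
  comp <- raw(256)
  comp[as.integer(charToRaw("ACGT")) + 1L] <- charToRaw("TGCA")
  rev(comp[as.integer(r) + 1L])
}

assert_dna <- function(x, what = "sequence") {
  bad <- gregexpr("[^ACGT]", x)[[1]]
  if (bad[1] != -1L)
    stop(what, " contains non-DNA characters at position(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  invisible(TRUE)
}

# codon -> amino acid lookup (standard genetic code), stops as '*'
.codon_table <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    gc
  }
})

#' Translate a DNA string in frame 1
#'
#' Trailing bases that do not fill a codon are dropped. Stops are
#' returned as `*`; codons containing non-ACGT letters as `X`.
#' @keywords internal
#' @noRd
translate_dna <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Random DNA avoiding stop-codon seeds
#'
#' When `coding_safe` is TRUE the sampler never emits a T followed by A
#' or G, so the result contains no stop codon (TAA/TAG/TGA) in any
#' reading frame or overlapping window.
#' @keywords internal
#' @noRd
random_dna <- function(n, coding_safe = FALSE) {
  if (n == 0L) return("")
  x <- sample(DNA_BASES, n, replace = TRUE)
  if (coding_safe) {
    afterT <- c(FALSE, x[-n] == "T") & x %in% c("A", "G")
    while (any(afterT)) {
      x[afterT] <- sample(c("C", "T"), sum(afterT), replace = TRUE)
      afterT <- c(FALSE, x[-n] == "T") & x %in% c("A", "G")
    }
  }
  paste(x, collapse = "")
}

# Substitute positions in a raw DNA vector with random different bases.
# Positions flagged 'constrained' refuse substitutions that would
# create a TA or TG dinucleotide (and hence possibly a stop codon) with
# either neighbour; if no base qualifies the position is left unchanged.
substitute_bases <- function(seqraw, pos, constrained = rep(FALSE, length(pos))) {
  n <- length(seqraw)
  for (i in seq_along(pos)) {
    p <- pos[i]
    old <- rawToChar(seqraw[p])
    cand <- setdiff(DNA_BASES, old)
    if (constrained[i]) {
      left  <- if (p > 1L) rawToChar(seqraw[p - 1L]) else ""
      right <- if (p < n) rawToChar(seqraw[p + 1L]) else ""
      if (left == "T") cand <- setdiff(cand, c("A", "G"))
      if (right %in% c("A", "G")) cand <- setdiff(cand, "T")
    }
    if (length(cand))
      seqraw[p] <- charToRaw(sample(cand, 1L))
  }
  seqraw
}
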