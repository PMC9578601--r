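# The bundled full-length HML-2 provirus template.
#
# Coordinates follow the reference frame used throughout the package:
# a ~9.5 kb 2-LTR provirus with the retroviral gene intervals of the
# full-length reference (gag 1112-3112, pro 2938-3918, pol 3915-6749,
# env 6451-8550, spliced rec 6451-6711 + 8411-8467 and np9
# 6451-6494 + 8411-8591) and 968-nt LTRs at 1-968 and 8505-9472. All
# coordinates are 1-based inclusive.
#
# The template sequence itself is synthetic: it is generated once,
# deterministically, with a sampler that avoids TA/TG dinucleotides in
# coding spans so that every viral gene translates without an internal
# stop codon, and the 3' LTR is a byte copy of the 5' LTR (as at
# integration). It is a stand-in for a real consensus provirus; a real
# reference sequence can be supplied wherever a template is accepted.

TEMPLATE_LENGTH <- 9472L
LTR_LENGTH <- 968L
LTR5_REGION <- c(1L, 968L)
LTR3_REGION <- c(8505L, 9472L)
LTR3_OFFSET <- 8504L          # LTR3 = LTR5 position + offset

# U3 / R / U5 sub-regions within a 968-nt LTR (LTR-local, 1-based).
# Transcription initiates at the U3-R border and polyadenylation at the
# R-U5 border.
LTR_U3 <- c(1L, 780L)
LTR_R  <- c(781L, 870L)
LTR_U5 <- c(871L, 968L)

TYPE1_DELETION_LENGTH <- 292L
# Default placement of the type 1 pol-env border deletion on the
# template: frameshifts env, truncates rec part 1, leaves both np9
# parts untouched and removes only an in-frame 60-nt tail from pol.
TYPE1_DELETION_START <- 6690L

LTR_SUBTYPES <- c("LTR5A", "LTR5B", "LTR5HS")
ESA_GROUPS <- c("Rhesus", "Gibbon", "Orangutan", "Gorilla", "Chimpanzee",
                "HumanFixed", "HumanPolymorphic")

#' Reference gene coordinate table
#'
#' Returns the retroviral gene intervals of the bundled full-length
#' reference, one row per gene part. `gag`, `pro`, `pol` and `env` are
#' single intervals; the spliced accessory genes `rec` and `np9` have
#' two parts each, concatenated 5' to 3' for translation. Coordinates
#' are 1-based inclusive nucleotide positions on the template.
#'
#' @return A data.frame with columns `gene`, `part`, `start`, `end`.
#' @export
hml2_genes <- function() {
  data.frame(
    gene  = c("gag", "pro", "pol", "env", "rec", "rec", "np9", "np9"),
    part  = c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 2L),
    start = c(1112L, 2938L, 3915L, 6451L, 6451L, 8411L, 6451L, 8411L),
    end   = c(3112L, 3918L, 6749L, 8550L, 6711L, 8467L, 6494L, 8591L),
    stringsAsFactors = FALSE
  )
}

# LTR-local positions (all >= 100, so their 3' LTR images fall outside
# every gene interval) that carry subtype-diagnostic bases. The
# template LTR is the LTR5HS baseline; LTR5A and LTR5B substitute at
# these sites.
.subtype_sites <- function() {
  pos <- seq(420L, 940L, by = 18L)          # 30 diagnostic sites in U3/R/U5
  list(positions = pos, n = length(pos))
}

# Toy transcription-factor motif words planted in LTR U3. Slots at the
# same LTR-local position carry the subtype-specific word of the LTR's
# subtype; COM* words are common to all subtypes. The subtype words
# are 10-mers so that a PWM match at p <= 1e-4 tolerates one
# substitution (divergence rarely erases a site). All words sit at
# LTR-local >= 120, outside every coding-sequence image, and are
# pairwise highly dissimilar within a position slot.
.motif_sites <- function() {
  data.frame(
    motif   = c("COM1", "COM2",
                "HS1", "HS2", "HS3",
                "A1", "A2", "A3",
                "B1", "B2", "B3"),
    subtype = c("all", "all",
                "LTR5HS", "LTR5HS", "LTR5HS",
                "LTR5A", "LTR5A", "LTR5A",
                "LTR5B", "LTR5B", "LTR5B"),
    ltr_pos = c(130L, 170L,
                230L, 280L, 330L,
                230L, 280L, 330L,
                230L, 280L, 330L),
    word    = c("AGGCCAAG", "CCGGAAGG",
                "GGACGTCAGC", "CAACGGCATT", "GCCGTTAAGG",
                "TTCAGCGTAA", "AGTGACTCCG", "CGATAGGCTT",
                "CCTTGTACGA", "GACCATGATC", "TGGCAACTGG"),
    stringsAsFactors = FALSE
  )
}

#' The bundled full-length provirus template
#'
#' Builds the package's deterministic ~9.5 kb 2-LTR provirus template:
#' the sequence, the gene coordinate table ([hml2_genes()]) and the LTR
#' intervals. The same object is accepted everywhere a reference
#' provirus is needed (genome construction, ORF projection, LTR
#' extraction).
#'
#' @param sequence Optional replacement DNA string of length 9472 (for
#'   example a real full-length provirus); gene and LTR coordinates are
#'   kept.
#' @return An object of class `hml2_template`: a list with elements
#'   `sequence`, `genes`, `ltr5`, `ltr3`, `length`.
#' @examples
#' tpl <- hml2_template()
#' nchar(tpl$sequence)
#' @export
hml2_template <- function(sequence = NULL) {
  if (is.null(sequence)) sequence <- .template_sequence()
  if (nchar(sequence) != TEMPLATE_LENGTH)
    stop("template sequence must be ", TEMPLATE_LENGTH, " nt, got ",
         nchar(sequence))
  assert_dna(sequence, "template sequence")
  structure(
    list(sequence = sequence,
         genes = hml2_genes(),
         ltr5 = LTR5_REGION,
         ltr3 = LTR3_REGION,
         length = TEMPLATE_LENGTH),
    class = "hml2_template"
  )
}

#' @export
print.hml2_template <- function(x, ...) {
  cat("HML-2 provirus template:", x$length, "nt;",
      nrow(x$genes), "gene parts; LTRs",
      paste(x$ltr5, collapse = "-"), "and",
      paste(x$ltr3, collapse = "-"), "\n")
  invisible(x)
}

# Deterministic construction of the template sequence (cached).
.template_cache <- new.env(parent = emptyenv())

.template_sequence <- function() {
  if (!is.null(.template_cache$seq)) return(.template_cache$seq)
  seq <- with_seed(880531L, {
    x <- strsplit(random_dna(TEMPLATE_LENGTH, coding_safe = TRUE), "")[[1]]
    x[1L] <- "C"                       # keeps the LTR3 copy junction stop-free
    # plant the common and LTR5HS motif words in the 5' LTR U3 (the
    # template LTR is the LTR5HS baseline)
    ms <- .motif_sites()
    for (i in which(ms$subtype %in% c("all", "LTR5HS"))) {
      p <- ms$ltr_pos[i]
      x[p:(p + nchar(ms$word[i]) - 1L)] <- strsplit(ms$word[i], "")[[1]]
    }
    # the 3' LTR is a byte copy of the 5' LTR
    x[LTR3_REGION[1]:LTR3_REGION[2]] <- x[LTR5_REGION[1]:LTR5_REGION[2]]
    paste(x, collapse = "")
  })
  .template_cache$seq <- seq
  seq
}
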