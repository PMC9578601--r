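Package: provex
Title: Locus-Resolved Endogenous Retrovirus (HERV-K HML-2) Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for locus-level analysis of human
    endogenous retrovirus (HERV-K HML-2) expression from RNA-seq.
    Includes a synthetic-data generator that plants families of
    near-identical proviruses (with long terminal repeat subtypes,
    type 1/2 structure, solo LTRs and controlled lesions) into a toy
    genome and emits multimapping read alignments with ground truth; an
    iterative mixture-model (EM) quantifier that reassigns multimapping
    reads to proviral loci and reports fractional counts and TPM;
    tissue, provirus-age and covariate expression profiling; open
    reading frame intactness annotation by coordinate projection
    through pairwise alignment; LTR neighbor-joining phylogeny and
    transcription-factor motif scanning with exact p-values plus
    presence-matrix clustering with bootstrap support; and a classifier
    of LTR-driven versus read-through transcription from read coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
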