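#!/usr/bin/env Rscript
# Stage 6: transcription mechanism classification.
#
# Pools primary alignments per provirus, computes read-start and depth
# profiles over the locus +/- 2 kb, and classifies each expressed
# provirus as LTR-driven (start enrichment at the U3-R border of its
# own 5' LTR or of an annotated upstream solo LTR, no upstream
# continuity) or read-through (coverage running in from upstream).
# Also correlates each provirus with host genes within 10 kb.

suppressMessages(library(provex))
datadir <- "results/data"

ann <- read_annotation(file.path(datadir, "annotation.tsv"))
md <- read_metadata(file.path(datadir, "metadata.tsv"))
recs <- do.call(rbind, lapply(md$sample, function(s)
  read_sam(file.path(datadir, paste0(s, ".sam")))$records))

tpm_tab <- read.delim("results/tpm.tsv")
tpm <- as.matrix(tpm_tab[, -1]); rownames(tpm) <- tpm_tab$locus_id
pv <- ann$locus_id[ann$class == "provirus"]
overall <- rowMeans(tpm[pv, , drop = FALSE])

calls <- do.call(rbind, lapply(pv, function(id) {
  pr <- coverage_profile(recs, ann, id, flank = 2000L)
  classify_mechanism(pr, ann, expressed = overall[id] >= 1)
}))
write.table(calls, "results/mechanism.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Mechanism calls:\n")
print(calls, row.names = FALSE, digits = 3)

em <- structure(list(counts = tpm, tpm = tpm,
                     lengths = ann$length[match(rownames(tpm), ann$locus_id)],
                     annotation = ann, metadata = md, tpm_universe = "all"),
                class = "expression_matrix")
corr <- neighbor_gene_correlation(em, window = 10000L)
if (nrow(corr)) {
  write.table(corr, "results/neighbor_correlation.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("\nProvirus-gene correlations within 10 kb:\n")
  print(corr, row.names = FALSE, digits = 3)
}
cat("Wrote results/mechanism.tsv and results/neighbor_correlation.tsv\n")
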