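#!/usr/bin/env Rscript
# Stage 1: build the synthetic study.
#
# Plants a small HML-2 provirus complement -- all three LTR subtypes,
# several ESA age groups, one type 1 provirus, one provirus driven by
# an upstream solo LTR (551 bp away), and one 5'-LTR-less provirus
# transcribed by read-through from a neighbouring host gene -- and
# simulates multimapping RNA-seq alignments for 6 donors x 3 tissues.
#
# Everything downstream is reproducible from results/data/: genome
# FASTA, annotation TSV, per-sample SAM, metadata TSV, truth TSVs.

suppressMessages(library(provex))
seed <- as.integer(Sys.getenv("PROVEX_SEED", "1"))
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

co <- demo_cohort(seed = seed, library_size = 20000L)
write_genome_fasta(co$genome, file.path(outdir, "genome.fasta"))
write_annotation(co$genome$annotation, file.path(outdir, "annotation.tsv"))
md <- emit_metadata(co$designs, file.path(outdir, "metadata.tsv"))

pv <- co$genome$annotation[co$genome$annotation$class != "host_gene", ]
seqs <- Biostrings::DNAStringSet(vapply(pv$locus_id, function(id)
  locus_sequence(co$genome, id), ""))
Biostrings::writeXStringSet(seqs, file.path(outdir, "proviruses.fasta"))

n_multi <- 0L; n_reads <- 0L
for (d in co$designs) {
  sim <- simulate_reads(
    co$genome, d,
    sam_path = file.path(outdir, paste0(d$sample_id, ".sam")),
    truth_path = file.path(outdir, paste0(d$sample_id, ".truth.tsv")))
  n_reads <- n_reads + nrow(sim$truth)
  n_multi <- n_multi + sum(table(sim$records$qname) > 1L)
}

ann <- co$genome$annotation
cat(sprintf("Planted %d proviruses, %d solo LTR(s), %d host genes on %d chromosomes.\n",
            sum(ann$class == "provirus"), sum(ann$class == "solo_LTR"),
            sum(ann$class == "host_gene"), length(co$genome$chroms)))
cat(sprintf("Simulated %d samples (%d donors x %d tissues), %d reads total;\n",
            length(co$designs), length(unique(md$donor)),
            length(unique(md$tissue)), n_reads))
cat(sprintf("%.1f%% of reads align to more than one location (multimapping).\n",
            100 * n_multi / n_reads))
cat("Wrote genome/annotation/metadata/SAM/truth under", outdir, "\n")
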