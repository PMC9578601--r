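# Interchange-format readers/writers and the end-to-end pipeline
# driver. All TSVs use 1-based inclusive coordinates and carry a
# comment header naming their units.

write_units_tsv <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", units,
                    "; coordinates 1-based inclusive where applicable"),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_units_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read the locus annotation table
#'
#' @param annotation Annotation data.frame ([build_genome()] layout).
#' @param path TSV path.
#' @return The path (write) or the annotation data.frame (read).
#' @export
write_annotation <- function(annotation, path) {
  write_units_tsv(annotation, path,
                  "locus annotation; start/end genomic nt; class provirus|solo_LTR|host_gene")
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- read_units_tsv(path)
  need <- c("locus_id", "chrom", "start", "end", "strand", "class")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (any(ann$end < ann$start))
    stop("annotation record with end < start: ",
         ann$locus_id[ann$end < ann$start][1])
  if (!"length" %in% names(ann)) ann$length <- ann$end - ann$start + 1L
  ann
}

#' Write / read sample metadata
#'
#' @param metadata Metadata data.frame ([emit_metadata()] layout).
#' @param path TSV path.
#' @export
write_metadata <- function(metadata, path) {
  write_units_tsv(metadata, path, "sample metadata; age in years; hardy 1-4")
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  md <- read_units_tsv(path)
  need <- c("sample", "tissue", "sex", "age", "age_group", "hardy")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  md
}

#' Write genome sequences as FASTA
#'
#' @param genome An `hml2_genome` (or named character vector).
#' @param path Output FASTA.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "hml2_genome")) genome$chroms else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Default run configuration
#'
#' Collects every tunable threshold of the pipeline with the package
#' defaults: expression threshold 1 TPM, motif p-value 1e-4,
#' significance level 0.05, 500 NJ and 1000 cluster bootstrap
#' replicates. The configuration round-trips losslessly through JSON.
#'
#' @param seed Global seed; each stochastic stage derives its own
#'   stream from it.
#' @param outdir Output directory.
#' @param ... Overrides of any default field.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = "provex_run", ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    expression_threshold = 1, motif_p = 1e-4, alpha = 0.05,
    nj_bootstrap = 500L, cluster_bootstrap = 1000L,
    tpm_universe = "all", prior_weight = 0, em_tol = 1e-6,
    em_max_iter = 1000L, temperature = 1,
    divergence = 0.02, library_size = 20000L, read_length = 75L,
    error_rate = 0.001, mismatch_budget = 3L)
  ovr <- list(...)
  cfg[names(ovr)] <- ovr
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

#' The bundled demonstration cohort
#'
#' A small study design exercising every pipeline stage: proviruses of
#' all three LTR subtypes and several ESA groups, a type 1 provirus, a
#' provirus driven by an upstream solo LTR, a read-through provirus
#' lacking its 5' LTR inside a host gene neighbourhood, and samples
#' from three tissues with sex/age/Hardy structure.
#'
#' @param seed Integer seed.
#' @param n_donors Donors per tissue set.
#' @param library_size Reads per sample.
#' @return List with `specs`, `genome`, `designs`, `tissue_types`.
#' @export
demo_cohort <- function(seed = 1L, n_donors = 6L, library_size = 20000L) {
  specs <- list(
    provirus_spec("1q21.3", "chr1", 6000L, ltr_subtype = "LTR5HS",
                  esa_group = "Gorilla"),
    provirus_spec("3q12.3", "chr1", 26000L, ltr_subtype = "LTR5HS",
                  esa_group = "Gorilla", type = 1L),
    provirus_spec("7q34", "chr1", 46000L, ltr_subtype = "LTR5A",
                  esa_group = "Gibbon"),
    provirus_spec("10p14", "chr1", 66000L, ltr_subtype = "LTR5A",
                  esa_group = "Orangutan"),
    provirus_spec("22q11.23", "chr2", 8000L, ltr_subtype = "LTR5B",
                  esa_group = "Chimpanzee",
                  upstream_driver_offset = 551L),
    provirus_spec("6q25.1", "chr2", 30000L, ltr_subtype = "LTR5HS",
                  esa_group = "HumanFixed", has_5ltr = FALSE,
                  mechanism = "read_through"),
    host_gene_spec("ASRGL1", "chr2", 24000L, length = 5500L),
    host_gene_spec("RAB5A", "chr2", 50000L, length = 3000L)
  )
  genome <- build_genome(specs, seed = child_seed(seed, 1L))
  tissues <- c("cerebellum", "testis", "blood")
  tissue_types <- c(cerebellum = "brain", testis = "reproductive",
                    blood = "circulatory")
  base_expr <- list(
    cerebellum = c("1q21.3" = 9, "3q12.3" = 10, "7q34" = 4, "10p14" = 3,
                   "22q11.23" = 0.5, "6q25.1" = 2, "ASRGL1" = 6,
                   "RAB5A" = 10),
    testis = c("1q21.3" = 8, "3q12.3" = 9, "7q34" = 0.1, "10p14" = 0,
               "22q11.23" = 6, "6q25.1" = 2, "ASRGL1" = 6, "RAB5A" = 10),
    blood = c("1q21.3" = 2, "3q12.3" = 2.5, "7q34" = 0, "10p14" = 0,
              "22q11.23" = 0.2, "6q25.1" = 0.1, "ASRGL1" = 6,
              "RAB5A" = 10))
  designs <- list()
  k <- 0L
  for (d in seq_len(n_donors)) {
    sex <- if (d %% 2L == 0L) "F" else "M"
    age <- 22L + 8L * (d - 1L)
    hardy <- 1L + (d - 1L) %% 4L
    for (tt in tissues) {
      k <- k + 1L
      expr <- base_expr[[tt]]
      # donor-level lognormal variation
      expr <- expr * with_seed(child_seed(seed, 100L + k),
                               stats::rlnorm(length(expr), 0, 0.25))
      # the read-through provirus rides its host-gene driver
      expr[["6q25.1"]] <- 0.35 * expr[["ASRGL1"]]
      designs[[k]] <- sample_design(
        sample_id = sprintf("D%02d_%s", d, tt),
        donor_id = sprintf("D%02d", d), tissue = tt, sex = sex,
        age = min(age, 70L), hardy = hardy, expression = expr,
        library_size = library_size,
        seed = child_seed(seed, 200L + k))
    }
  }
  list(specs = specs, genome = genome, designs = designs,
       tissue_types = tissue_types)
}

#' Run the full pipeline
#'
#' Executes simulate -> quantify -> profiles -> ORF annotation -> LTR
#' phylogeny and motif clustering -> mechanism classification on the
#' bundled demonstration cohort, writing every stage's tables plus a
#' provenance manifest to `cfg$outdir`. Any stage failure halts with
#' the stage name; tables written so far are preserved.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(package = "provex",
                   version = as.character(utils::packageVersion("provex")),
                   seed = cfg$seed, config = unclass(cfg),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  co <- stage("simulate", {
    co <- demo_cohort(seed = cfg$seed, library_size = cfg$library_size)
    write_annotation(co$genome$annotation,
                     file.path(cfg$outdir, "annotation.tsv"))
    write_genome_fasta(co$genome, file.path(cfg$outdir, "genome.fasta"))
    md <- emit_metadata(co$designs, file.path(cfg$outdir, "metadata.tsv"))
    co$metadata <- md
    co$sims <- lapply(co$designs, function(d)
      simulate_reads(co$genome, d,
                     sam_path = file.path(cfg$outdir,
                                          paste0(d$sample_id, ".sam")),
                     mismatch_budget = cfg$mismatch_budget))
    names(co$sims) <- vapply(co$designs, `[[`, "", "sample_id")
    co
  })

  em <- stage("quantify", {
    em <- quantify_cohort(lapply(co$sims, `[[`, "records"),
                          co$genome$annotation, co$metadata,
                          tpm_universe = cfg$tpm_universe,
                          prior_weight = cfg$prior_weight,
                          tol = cfg$em_tol, max_iter = cfg$em_max_iter,
                          temperature = cfg$temperature)
    write_units_tsv(data.frame(locus_id = rownames(em$counts),
                               round(em$counts, 3)),
                    file.path(cfg$outdir, "counts.tsv"),
                    "fractional read counts")
    write_units_tsv(data.frame(locus_id = rownames(em$tpm),
                               round(em$tpm, 3)),
                    file.path(cfg$outdir, "tpm.tsv"),
                    "expression in TPM")
    em
  })

  prof <- stage("profiles", {
    pvrows <- provirus_rows(em)
    calls <- call_expressed(em$tpm[pvrows, , drop = FALSE], em$metadata,
                            threshold = cfg$expression_threshold)
    ts <- tissue_summary(em, threshold = cfg$expression_threshold)
    pat <- pattern_classify(calls$expressed, co$tissue_types)
    esa <- esa_breakdown(em)
    cov <- covariate_tests(em, "sex", alpha = cfg$alpha)
    write_units_tsv(ts$tissues, file.path(cfg$outdir, "tissue_summary.tsv"),
                    "per-tissue total provirus expression in TPM")
    write_units_tsv(data.frame(locus_id = names(pat), pattern = pat),
                    file.path(cfg$outdir, "patterns.tsv"),
                    "tissue expression pattern classes")
    write_units_tsv(esa$breakdown, file.path(cfg$outdir, "esa_breakdown.tsv"),
                    "expression by ESA age group; share in percent")
    if (!is.null(cov$tests))
      write_units_tsv(cov$tests, file.path(cfg$outdir, "covariate_sex.tsv"),
                      "Welch/ANOVA tests on log2(TPM+1); p-values BH-adjusted")
    list(calls = calls, summary = ts, patterns = pat, esa = esa, cov = cov)
  })

  orfs <- stage("orfs", {
    pv <- co$genome$annotation[co$genome$annotation$class == "provirus", ]
    seqs <- stats::setNames(lapply(pv$locus_id, locus_sequence,
                                   genome = co$genome), pv$locus_id)
    types <- stats::setNames(pv$type, pv$locus_id)
    rep <- orf_report(seqs, types = types, template = co$genome$template)
    write_units_tsv(rep, file.path(cfg$outdir, "orf_report.tsv"),
                    "ORF intactness verdicts")
    rep
  })

  ltr <- stage("ltr", {
    ltrs <- extract_ltrs(co$genome)
    msa <- ltr_msa(ltrs, template = co$genome$template)
    tree <- nj_ltr_tree(msa, bootstrap = cfg$nj_bootstrap,
                        seed = child_seed(cfg$seed, 31L))
    ape::write.tree(tree, file.path(cfg$outdir, "ltr_tree.nwk"))
    motifs <- hml2_toy_motifs()
    pres <- motif_presence(ltrs, motifs, p_threshold = cfg$motif_p)
    cl <- motif_cluster(pres, bootstrap = cfg$cluster_bootstrap,
                        seed = child_seed(cfg$seed, 32L))
    write_units_tsv(data.frame(ltr_id = rownames(pres), pres),
                    file.path(cfg$outdir, "motif_matrix.tsv"),
                    "binary motif presence (p <= motif threshold)")
    write_units_tsv(cl$clades, file.path(cfg$outdir, "motif_clades.tsv"),
                    "clade bootstrap supports in [0,1]")
    list(ltrs = ltrs, msa = msa, tree = tree, presence = pres,
         clustering = cl)
  })

  mech <- stage("mechanism", {
    pv <- co$genome$annotation[co$genome$annotation$class == "provirus", ]
    # pool primary alignments across samples per locus
    all_rec <- do.call(rbind, lapply(co$sims, `[[`, "records"))
    overall <- rowMeans(em$tpm[pv$locus_id, , drop = FALSE])
    calls <- do.call(rbind, lapply(pv$locus_id, function(id) {
      prof_ <- coverage_profile(all_rec, co$genome$annotation, id)
      classify_mechanism(prof_, co$genome$annotation,
                         expressed = overall[id] >=
                           cfg$expression_threshold)
    }))
    corr <- neighbor_gene_correlation(em)
    write_units_tsv(calls, file.path(cfg$outdir, "mechanism.tsv"),
                    "mechanism calls; enrichment/continuity ratios")
    if (nrow(corr))
      write_units_tsv(corr, file.path(cfg$outdir, "neighbor_correlation.tsv"),
                      "Pearson r of log2(TPM+1); BH-adjusted p")
    list(calls = calls, correlation = corr)
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$outputs <- list.files(cfg$outdir)
  sams <- list.files(cfg$outdir, pattern = "\\.sam$", full.names = TRUE)
  manifest$input_digests <- as.list(tools::md5sum(sams))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = co, expression = em, profiles = prof,
                 orfs = orfs, ltr = ltr, mechanism = mech,
                 manifest = manifest))
}
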