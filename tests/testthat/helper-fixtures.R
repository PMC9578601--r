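# Shared fixture builders. Everything is generated in code at test
# time; fixed seeds keep the suite deterministic.

# a small genome with n same-template proviruses on one chromosome
tiny_genome <- function(n = 2L, seed = 101L, divergence = 0.02, ...) {
  specs <- lapply(seq_len(n), function(i)
    provirus_spec(sprintf("pv%02d", i), "chr1",
                  6000L + (i - 1L) * 20000L, ...))
  build_genome(specs, seed = seed, divergence = divergence)
}

# an alignment_set built directly from candidate tuples, bypassing SAM
manual_alignment_set <- function(read, locus, score,
                                 loci = sort(unique(locus))) {
  structure(list(
    candidates = data.frame(read = read, locus = locus,
                            score = as.numeric(score),
                            stringsAsFactors = FALSE),
    loci = loci, n_reads = length(unique(read)),
    sample_id = "manual"),
    class = "alignment_set")
}

# observed-data log-likelihood of the EM mixture for given pi
# (independent of the EM implementation's internals)
mixture_loglik <- function(pi, q_by_read) {
  sum(vapply(q_by_read, function(qi)
    log(sum(pi[names(qi)] * qi / sum(qi))), 1))
}

# dense grid search over the K-simplex at the given resolution,
# maximising the same observed-data likelihood -- the brute-force
# oracle for small EM instances
grid_search_pi <- function(q_by_read, K, resolution = 1e-3) {
  steps <- round(1 / resolution)
  stopifnot(K %in% c(2L, 3L))
  if (K == 2L) {
    a <- 0:steps
    grid <- cbind(a, steps - a) / steps
  } else {
    a <- unlist(lapply(0:steps, function(i) rep(i, steps - i + 1L)))
    b <- unlist(lapply(0:steps, function(i) 0:(steps - i)))
    grid <- cbind(a, b, steps - a - b) / steps
  }
  loci <- sort(unique(unlist(lapply(q_by_read, names))))
  colnames(grid) <- loci
  # vectorised: log-lik = sum_i log(grid %*% q_i / sum(q_i))
  ll <- numeric(nrow(grid))
  for (qi in q_by_read) {
    v <- as.vector(grid[, names(qi), drop = FALSE] %*% (qi / sum(qi)))
    v[v <= 0] <- .Machine$double.xmin
    ll <- ll + log(v)
  }
  grid[which.max(ll), ]
}

# q weights grouped per read from an alignment_set at temperature 1
q_by_read_of <- function(aln) {
  sp <- split(seq_len(nrow(aln$candidates)), aln$candidates$read)
  lapply(sp, function(ix) {
    q <- exp(aln$candidates$score[ix] - max(aln$candidates$score[ix]))
    names(q) <- aln$candidates$locus[ix]
    q
  })
}

# random additive distance matrix from a random tree topology;
# returns list(tree, D)
random_additive_case <- function(n_taxa, seed) {
  tr <- withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    tr
  })
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# direct translation of a template-coordinate interval of a sequence
# that carries only substitutions (no indels) -- an oracle independent
# of alignment/projection
oracle_translate_interval <- function(sequence, start, end) {
  x <- substr(sequence, start, end)
  n <- nchar(x) %/% 3L
  codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(Biostrings::GENETIC_CODE[codons])
}
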