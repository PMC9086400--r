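# Small programmatic fixtures shared across test files.

# Build a one-population geno_matrix from a call matrix and positions.
make_gm <- function(calls, pos_bp = NULL, chrom = NULL, population = "pop1") {
  calls <- as.matrix(calls)
  n_snp <- ncol(calls)
  if (is.null(pos_bp)) pos_bp <- seq_len(n_snp) * 1e5
  if (is.null(chrom)) chrom <- rep(1L, n_snp)
  geno_matrix(
    calls,
    samples = data.frame(sample_id = sprintf("s%d", seq_len(nrow(calls))),
                         population = population),
    map = data.frame(snp_id = sprintf("m%d", seq_len(n_snp)),
                     chrom = chrom, pos_bp = pos_bp,
                     allele_a = "A", allele_b = "C"))
}

# Random call matrix with missingness, for oracle comparisons.
random_gm <- function(n_sample, n_snp, missing_rate = 0.05, n_chrom = 2,
                      spacing = 1e5) {
  calls <- matrix(sample(0:2, n_sample * n_snp, replace = TRUE,
                         prob = c(0.4, 0.25, 0.35)),
                  nrow = n_sample)
  calls[runif(length(calls)) < missing_rate] <- NA_integer_
  per_chrom <- ceiling(n_snp / n_chrom)
  chrom <- rep(seq_len(n_chrom), each = per_chrom)[seq_len(n_snp)]
  pos <- unlist(lapply(split(seq_len(n_snp), chrom), function(ii) {
    sort(sample(seq_len(per_chrom * 3), length(ii))) * spacing
  }), use.names = FALSE)
  make_gm(calls, pos_bp = pos, chrom = chrom)
}

# A tiny deterministic cohort with annotations/outgroup for pipeline tests.
small_sim <- function(seed = 42, ...) {
  sim_cohort(sim_config(n_chrom = 2, chrom_length_bp = 20e6,
                        snp_spacing_bp = 25000, founder_count = 20,
                        seed = seed, ...))
}

# Build a 5-sample window whose B-allele column sums are `j`, so that S and
# pi are known exactly (n = 10 haplotypes, no missing calls).
window_gm_from_counts <- function(j_counts) {
  calls <- vapply(j_counts, function(j) {
    g <- integer(5)
    full <- j %/% 2
    if (full > 0) g[seq_len(full)] <- 2L
    if (j %% 2 == 1) g[full + 1] <- 1L
    g
  }, integer(5))
  make_gm(calls, pos_bp = seq_along(j_counts) * 1e4)
}
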