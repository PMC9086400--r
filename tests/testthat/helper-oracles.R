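# Independent reference implementations used to cross-check the package.
# These deliberately recompute everything from scratch (cumulative sums and
# whole-window recounts instead of incremental counters) so they share no
# mechanics with the production code.

# Exhaustive consecutive-method scanner for one sample on one chromosome.
# Returns a matrix with columns start_idx, end_idx (or NULL).
oracle_scan_chrom <- function(gt, pos, params) {
  if (params$run_type == "ROH") {
    conf <- !is.na(gt) & gt != 1L
    opp <- !is.na(gt) & gt == 1L
  } else {
    conf <- !is.na(gt) & gt == 1L
    opp <- !is.na(gt) & gt != 1L
  }
  miss <- is.na(gt)
  n <- length(gt)
  co <- cumsum(opp)
  cm <- cumsum(miss)
  gap_bad <- c(FALSE, diff(pos) > params$max_gap_bp)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (!conf[i]) { i <- i + 1L; next }
    if (i < n) {
      ks <- (i + 1L):n
      bad <- ks[gap_bad[ks] | (co[ks] - co[i]) > params$max_opposite |
                  (cm[ks] - cm[i]) > params$max_missing]
      k <- if (length(bad)) bad[1] else n + 1L
    } else {
      k <- n + 1L
    }
    end <- k - 1L
    while (end > i && !conf[end]) end <- end - 1L
    n_thr <- if (params$conforming_only_min_snps) {
      sum(conf[i:end])
    } else {
      end - i + 1L
    }
    if (n_thr >= params$min_snps && pos[end] - pos[i] + 1 >= params$min_length_bp) {
      out <- rbind(out, c(i, end))
    }
    i <- if (k > n) k else if (gap_bad[k]) k else k + 1L
  }
  out
}

# Full-cohort oracle returning the same layout as detect_runs().
oracle_detect_runs <- function(gm, params) {
  res <- list()
  for (s in seq_len(nrow(gm$samples))) {
    for (cc in unique(gm$map$chrom)) {
      idx <- which(gm$map$chrom == cc)
      m <- oracle_scan_chrom(gm$calls[s, idx], gm$map$pos_bp[idx], params)
      if (is.null(m)) next
      res[[length(res) + 1]] <- data.frame(
        sample_id = gm$samples$sample_id[s], chrom = cc,
        start_bp = gm$map$pos_bp[idx[m[, 1]]],
        end_bp = gm$map$pos_bp[idx[m[, 2]]])
    }
  }
  if (!length(res)) {
    return(data.frame(sample_id = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric()))
  }
  do.call(rbind, res)
}

# Literal reapplication of the four QC rules, loop-based.
oracle_qc <- function(gm, cfg) {
  keep_snp <- rep(TRUE, nrow(gm$map))
  if (cfg$autosomes_only) {
    for (j in seq_along(keep_snp)) {
      keep_snp[j] <- gm$map$chrom[j] >= 1 && gm$map$chrom[j] <= cfg$n_autosomes
    }
  }
  calls <- gm$calls[, keep_snp, drop = FALSE]
  keep_sample <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    keep_sample[i] <- mean(!is.na(calls[i, ])) >= cfg$min_sample_call_rate
  }
  calls <- calls[keep_sample, , drop = FALSE]
  keep2 <- rep(TRUE, ncol(calls))
  for (j in seq_len(ncol(calls))) {
    keep2[j] <- mean(!is.na(calls[, j])) >= cfg$min_snp_call_rate
  }
  calls <- calls[, keep2, drop = FALSE]
  keep3 <- rep(TRUE, ncol(calls))
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j][!is.na(calls[, j])]
    if (!length(g)) { keep3[j] <- FALSE; next }
    p <- sum(g) / (2 * length(g))
    keep3[j] <- min(p, 1 - p) >= cfg$min_maf
  }
  list(sample_ids = rownames(calls),
       snp_ids = colnames(calls)[keep3])
}

# Hand-summed Tajima constant chain (textbook formulas, written out).
oracle_tajima_d <- function(n, S, pi) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Point-in-interval recount of run incidence for one population.
oracle_incidence <- function(runs, gm, pop) {
  ids <- gm$samples$sample_id[gm$samples$population == pop]
  vapply(seq_len(nrow(gm$map)), function(j) {
    cc <- gm$map$chrom[j]; pp <- gm$map$pos_bp[j]
    covered <- vapply(ids, function(id) {
      rr <- runs[runs$sample_id == id, ]
      any(rr$chrom == cc & rr$start_bp <= pp & rr$end_bp >= pp)
    }, logical(1))
    100 * sum(covered) / length(ids)
  }, numeric(1))
}

# Brute-force pairwise interval intersection (per chromosome).
oracle_intersect <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start_bp[i], b$start_bp[j])
      e <- min(a$end_bp[i], b$end_bp[j])
      if (s <= e) out <- rbind(out, data.frame(chrom = a$chrom[i],
                                               start_bp = s, end_bp = e))
    }
  }
  out
}
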