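#' Tajima's D normalizing constants
#'
#' @param n Number of sequences (haplotypes).
#' @return A named list: a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 4)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Tile (chrom, pos) into fixed windows starting at 1.
window_index <- function(pos_bp, window_bp) floor((pos_bp - 1) / window_bp)

site_stats <- function(gm) {
  cl <- gm$calls
  n_called <- unname(colSums(!is.na(cl)))
  j <- unname(colSums(cl, na.rm = TRUE))  # B-allele count
  n_s <- 2 * n_called                     # chromosomes observed at the site
  tibble::tibble(chrom = gm$map$chrom, pos_bp = gm$map$pos_bp,
                 snp_id = gm$map$snp_id, n_s = n_s, j = as.numeric(j),
                 segregating = n_s > 0 & j > 0 & j < n_s,
                 pi_site = ifelse(n_s > 1, 2 * j * (n_s - j) /
                                    (n_s * (n_s - 1)), 0))
}

#' Windowed Tajima's D
#'
#' Tiles each chromosome into non-overlapping windows of `window_bp`
#' (default 250 kb) and computes, per window, the segregating-site count S,
#' the mean number of pairwise differences pi (summed per-site
#' `2 j (n_s - j) / (n_s (n_s - 1))` with `j` the alternate-allele count and
#' `n_s` the non-missing chromosome count at the site), Watterson's
#' `theta_W = S / a1`, and `D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1))`
#' with the constants of [tajima_constants()] at `n = 2 x samples`. Windows
#' with `S = 0` are flagged undefined.
#'
#' @param gm A [geno_matrix()] with at least 2 samples (4 haplotypes).
#' @param window_bp Window width in bp.
#' @return A tibble: `chrom`, `win_start_bp`, `win_end_bp`, `n_snps`, `S`,
#'   `pi`, `D`, `D_undefined`.
#' @export
tajimas_d_windows <- function(gm, window_bp = 250000) {
  stopifnot(inherits(gm, "geno_matrix"))
  n <- 2 * nrow(gm$samples)
  if (n < 4) stop("need at least 4 haplotypes (2 samples)", call. = FALSE)
  k <- tajima_constants(n)
  site_stats(gm) %>%
    dplyr::mutate(win = window_index(.data$pos_bp, window_bp)) %>%
    dplyr::group_by(.data$chrom, .data$win) %>%
    dplyr::summarise(
      n_snps = dplyr::n(),
      S = sum(.data$segregating),
      pi = sum(.data$pi_site[.data$segregating]),
      .groups = "drop") %>%
    dplyr::mutate(
      win_start_bp = .data$win * window_bp + 1,
      win_end_bp = (.data$win + 1) * window_bp,
      theta_w = .data$S / k$a1,
      D = ifelse(.data$S >= 1,
                 (.data$pi - .data$theta_w) /
                   sqrt(k$e1 * .data$S + k$e2 * .data$S * (.data$S - 1)),
                 NA_real_),
      D_undefined = .data$S == 0) %>%
    dplyr::select("chrom", "win_start_bp", "win_end_bp", "n_snps", "S",
                  "pi", "theta_w", "D", "D_undefined")
}

#' Parameters for the folded beta balancing-selection statistic
#'
#' @param similarity_exponent Exponent of the folded-frequency similarity
#'   weight `w_i = ((0.5 - |f_i - f_c|) / 0.5)^p`; 0 gives flat weights (and
#'   beta identically 0), larger values concentrate the weight on SNPs with
#'   frequencies close to the core's.
#' @param min_core_maf Minimum folded frequency for a SNP to serve as a core.
#' @param max_snp_distance_bp Maximum distance of a supporting SNP from the
#'   core; `NULL` (default) means the window width.
#' @return A list of class `beta_params`.
#' @export
beta_params <- function(similarity_exponent = 2, min_core_maf = 0.05,
                        max_snp_distance_bp = NULL) {
  stopifnot(similarity_exponent >= 0)
  structure(list(similarity_exponent = similarity_exponent,
                 min_core_maf = min_core_maf,
                 max_snp_distance_bp = max_snp_distance_bp),
            class = "beta_params")
}

#' Windowed folded beta statistic
#'
#' A folded allele-frequency-correlation scan for long-term balancing
#' selection. For each core SNP (folded frequency at least `min_core_maf`)
#' the surrounding SNPs i in the window are weighted by their frequency
#' similarity to the core, `w_i = ((0.5 - |f_i - f_c|) / 0.5)^p` on folded
#' frequencies. The weighted site count is turned into a theta estimate by
#' normalizing with the weight expected per unit theta under the neutral
#' folded frequency spectrum,
#' `D_norm = sum_j w(j/n) (1/j + 1/(n-j)) / (1 + [j = n-j])` over
#' `j = 1..floor(n/2)`, and compared with Watterson's unweighted estimate:
#' `beta(core) = sum_i w_i / D_norm - S / a1`. An excess of SNPs at
#' frequencies close to the core (the footprint of balancing selection)
#' gives beta > 0; with a flat weight function (`similarity_exponent = 0`)
#' `D_norm = a1` and beta is identically 0. The window score is the mean
#' over its core SNPs; windows with no eligible core, or whose cores have no
#' supporting SNP, are flagged undefined.
#'
#' @param gm A [geno_matrix()].
#' @param params A [beta_params()].
#' @param window_bp Window width in bp.
#' @return A tibble: `chrom`, `win_start_bp`, `win_end_bp`, `n_snps`,
#'   `n_cores`, `beta`, `beta_undefined`.
#' @export
beta_windows <- function(gm, params = beta_params(), window_bp = 250000) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(params, "beta_params"))
  n <- 2 * nrow(gm$samples)
  if (n < 4) stop("need at least 4 haplotypes (2 samples)", call. = FALSE)
  max_dist <- params$max_snp_distance_bp %||% window_bp
  p_w <- params$similarity_exponent
  a1 <- tajima_constants(n)$a1
  jj <- seq_len(floor(n / 2))
  c_j <- (1 / jj + 1 / (n - jj)) / (1 + (jj == n - jj))
  f_j <- jj / n

  af <- allele_frequencies(gm)
  af$folded <- pmin(af$freq_b, 1 - af$freq_b)
  af <- af[!is.na(af$folded), ]
  af$win <- window_index(af$pos_bp, window_bp)

  groups <- split(seq_len(nrow(af)),
                  paste(af$chrom, af$win, sep = ":"), drop = TRUE)
  out <- purrr::map_dfr(groups, function(idx) {
    fw <- af$folded[idx]
    pos <- af$pos_bp[idx]
    cores <- which(fw >= params$min_core_maf)
    betas <- vapply(cores, function(ci) {
      others <- which(abs(pos - pos[ci]) <= max_dist)
      others <- setdiff(others, ci)
      if (!length(others)) return(NA_real_)
      w <- ((0.5 - abs(fw[others] - fw[ci])) / 0.5)^p_w
      d_norm <- sum(((0.5 - abs(f_j - fw[ci])) / 0.5)^p_w * c_j)
      sum(w) / d_norm - length(others) / a1
    }, numeric(1))
    betas <- betas[!is.na(betas)]
    tibble::tibble(chrom = af$chrom[idx[1]], win = af$win[idx[1]],
                   n_snps = length(idx), n_cores = length(betas),
                   beta = if (length(betas)) mean(betas) else NA_real_,
                   beta_undefined = length(betas) == 0)
  })
  out %>%
    dplyr::mutate(win_start_bp = .data$win * window_bp + 1,
                  win_end_bp = (.data$win + 1) * window_bp) %>%
    dplyr::arrange(.data$chrom, .data$win_start_bp) %>%
    dplyr::select("chrom", "win_start_bp", "win_end_bp", "n_snps",
                  "n_cores", "beta", "beta_undefined")
}

#' Genome-wide Z-scores and upper-tail p-values for window statistics
#'
#' Standardizes each statistic over all windows where it is defined
#' (`z = (x - mean) / sd`) and converts to upper-tail standard-normal
#' p-values (large positive D or beta being the balancing-selection
#' candidates); windows with `p < 0.05` are flagged extreme.
#'
#' @param stats A window tibble from [tajimas_d_windows()],
#'   [beta_windows()], or a join of both.
#' @param columns Statistic columns to standardize; defaults to whichever of
#'   `"D"` and `"beta"` are present.
#' @return `stats` with, per statistic x, columns `z_x`, `p_x`, `extreme_x`.
#' @export
zscore_pvalues <- function(stats, columns = intersect(c("D", "beta"),
                                                      names(stats))) {
  if (!length(columns)) stop("no statistic columns found", call. = FALSE)
  for (col in columns) {
    x <- stats[[col]]
    ok <- is.finite(x)
    if (sum(ok) < 2) {
      stop("fewer than 2 defined windows for ", col, call. = FALSE)
    }
    s <- stats::sd(x[ok])
    if (s == 0) stop("zero variance in ", col, call. = FALSE)
    z <- (x - mean(x[ok])) / s
    p <- stats::pnorm(z, lower.tail = FALSE)
    stats[[paste0("z_", col)]] <- z
    stats[[paste0("p_", col)]] <- p
    stats[[paste0("extreme_", col)]] <- !is.na(p) & p < 0.05
  }
  stats
}

#' Joint Tajima's D and beta scan
#'
#' Convenience wrapper running [tajimas_d_windows()] and [beta_windows()] on
#' the same tiling, joining them, and standardizing both with
#' [zscore_pvalues()].
#'
#' @inheritParams beta_windows
#' @return A window tibble with D, beta, Z-scores, p-values and extreme
#'   flags.
#' @export
balancing_scan <- function(gm, params = beta_params(), window_bp = 250000) {
  d <- tajimas_d_windows(gm, window_bp)
  b <- beta_windows(gm, params, window_bp)
  zscore_pvalues(dplyr::full_join(
    d, b, by = c("chrom", "win_start_bp", "win_end_bp"),
    suffix = c("_d", "_beta")))
}
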