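#' SNP-based inbreeding coefficient F_HOM
#'
#' Computes, per individual, the excess-homozygosity coefficient
#' `F_HOM = (H_O - H_E) / (L - H_E)` over that individual's non-missing
#' autosomal SNPs: `H_O` is the observed homozygote count, `L` the number of
#' genotyped SNPs, and `H_E` the expected homozygote count
#' `sum_snp [1 - 2 p (1 - p) * 2 N_s / (2 N_s - 1)]` using the sample-wide
#' allele frequency `p` and non-missing genotype count `N_s` at each SNP
#' (the small-sample correction of the method-of-moments estimator).
#'
#' @param gm A [geno_matrix()] with at least two samples.
#' @param sample_size_correction Multiply expected heterozygosity by
#'   `2 N_s / (2 N_s - 1)` (default TRUE).
#' @return A tibble with one row per sample: `sample_id`, `population`,
#'   `H_O`, `H_E`, `L`, `F_HOM` and `undefined` (TRUE when `L == H_E`,
#'   i.e. a degenerate monomorphic panel).
#' @export
f_hom <- function(gm, sample_size_correction = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(gm$samples) < 2) {
    stop("F_HOM needs at least 2 samples (sample-size correction)",
         call. = FALSE)
  }
  cl <- gm$calls
  n_s <- colSums(!is.na(cl))
  p <- ifelse(n_s > 0, colSums(cl, na.rm = TRUE) / (2 * n_s), NA_real_)
  corr <- if (sample_size_correction) {
    ifelse(n_s > 0, 2 * n_s / (2 * n_s - 1), NA_real_)
  } else {
    rep(1, length(n_s))
  }
  exp_hom_snp <- 1 - 2 * p * (1 - p) * corr  # per-SNP expected homozygosity

  nonmiss <- !is.na(cl)
  H_O <- unname(rowSums(cl == 0L | cl == 2L, na.rm = TRUE))
  H_E <- as.vector(nonmiss %*% ifelse(is.na(exp_hom_snp), 0, exp_hom_snp))
  L <- unname(rowSums(nonmiss))
  denom <- L - H_E
  undefined <- abs(denom) < 1e-12
  tibble::tibble(
    sample_id = gm$samples$sample_id,
    population = gm$samples$population,
    H_O = H_O, H_E = H_E, L = as.integer(L),
    F_HOM = ifelse(undefined, NA_real_, (H_O - H_E) / denom),
    undefined = undefined
  )
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' `F_ROH = L_ROH / L_auto`: the summed length of an individual's ROH divided
#' by the autosomal genome length covered by SNPs (2.46 Gb for the goat
#' ARS1 autosomes; always taken from `build` so other genomes scale
#' correctly). The per-length-class decomposition restricts the numerator to
#' runs of one class, so class values sum exactly to the total.
#'
#' @param runs ROH tibble from [detect_runs()].
#' @param build A [genome_build()] or a single total-autosome length in bp.
#' @param samples Optional tibble (`sample_id`, `population`) giving the full
#'   cohort so run-free individuals get `F_ROH = 0`; defaults to the samples
#'   present in `runs`.
#' @return A tibble per sample: `sample_id`, `population`, `F_ROH` and one
#'   `F_ROH_<class>` column per ROH length class.
#' @export
f_roh <- function(runs, build, samples = NULL) {
  if (nrow(runs) && !all(runs$run_type == "ROH")) {
    stop("f_roh() expects ROH-type runs", call. = FALSE)
  }
  L_auto <- total_autosome_bp(build)
  if (is.null(samples)) {
    samples <- dplyr::distinct(runs[, c("sample_id", "population")])
  }
  cls <- run_length_classes("ROH")
  per_class <- runs %>%
    dplyr::mutate(class_label = as.character(
      run_length_class(.data$length_bp, "ROH"))) %>%
    dplyr::group_by(.data$sample_id, .data$class_label) %>%
    dplyr::summarise(len = sum(.data$length_bp), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "class_label", values_from = "len",
                       values_fill = 0)
  for (lab in cls$class_label) {
    if (!lab %in% names(per_class)) per_class[[lab]] <- rep(0, nrow(per_class))
  }
  out <- samples %>%
    dplyr::left_join(per_class, by = "sample_id") %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(cls$class_label),
                                ~ dplyr::coalesce(.x, 0) / L_auto))
  out$F_ROH <- rowSums(out[, cls$class_label, drop = FALSE])
  names(out)[match(cls$class_label, names(out))] <-
    paste0("F_ROH_", cls$class_label)
  dplyr::relocate(out, "F_ROH", .after = "population")
}

#' Pearson correlation with a t-test p-value
#'
#' @param x,y Paired numeric vectors (at least 3 complete finite pairs).
#' @return A one-row tibble: `r`, `p_value`, `n`, `df`, and `undefined`
#'   (TRUE when either variable has zero variance or fewer than 3 pairs
#'   remain, in which case `r` and `p_value` are `NA`).
#' @export
#' @examples
#' correlate(1:10, (1:10)^2)
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n,
                          df = max(n - 2L, 0L), undefined = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n,
                 df = unname(ct$parameter), undefined = FALSE)
}

#' Date inbreeding events from ROH length
#'
#' Under the classical expectation that an autozygous segment inherited from a
#' common ancestor `g` generations back has length `L = 100 / (2 g)` cM, a run
#' of `length_mb` megabases (with `cM_per_Mb` centimorgans per megabase,
#' default 1) points to `g = 100 / (2 * length_mb * cM_per_Mb)` generations.
#' A 16 Mb ROH thus dates to about 3 whole generations ago and an 8 Mb ROH to
#' about 6.
#'
#' @param length_mb Run length(s) in Mb, positive.
#' @param cM_per_Mb Map scale in cM/Mb.
#' @return A tibble: `length_mb`, `cM_per_Mb`, `g` (continuous) and
#'   `whole_generations` (`floor(g)`).
#' @export
#' @examples
#' generations_from_length(c(16, 8))
generations_from_length <- function(length_mb, cM_per_Mb = 1) {
  if (any(!is.finite(length_mb)) || any(length_mb <= 0)) {
    stop("length_mb must be positive", call. = FALSE)
  }
  g <- 100 / (2 * length_mb * cM_per_Mb)
  tibble::tibble(length_mb = length_mb, cM_per_Mb = cM_per_Mb, g = g,
                 whole_generations = as.integer(floor(g)))
}

#' Combine F_HOM and F_ROH and correlate them
#'
#' @param fhom Output of [f_hom()].
#' @param froh Output of [f_roh()].
#' @return A list: `per_sample` (joined tibble) and `correlations` (tibble of
#'   Pearson r of F_HOM against F_ROH overall and per length class).
#' @export
inbreeding_summary <- function(fhom, froh) {
  joined <- dplyr::inner_join(fhom, froh,
                              by = c("sample_id", "population"))
  froh_cols <- grep("^F_ROH", names(joined), value = TRUE)
  cors <- purrr::map_dfr(froh_cols, function(col) {
    dplyr::mutate(correlate(joined$F_HOM, joined[[col]]),
                  pair = paste0("F_HOM~", col), .before = 1)
  })
  list(per_sample = joined, correlations = cors)
}
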