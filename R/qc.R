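#' Quality-control configuration
#'
#' Defaults reproduce a standard SNP-chip cleaning: autosomal SNPs only,
#' sample and SNP call rate at least 0.90, minor allele frequency at least
#' 0.01, and deliberately no Hardy-Weinberg filter (inbreeding itself causes
#' HWE deviation, which is the signal being studied).
#'
#' @param min_snp_call_rate,min_sample_call_rate Fractions in \[0, 1\].
#' @param min_maf Minimum minor allele frequency in \[0, 1\].
#' @param autosomes_only Drop SNPs with non-positive or out-of-range
#'   chromosome labels (unmapped = 0, sex chromosomes coded above
#'   `n_autosomes`).
#' @param n_autosomes Highest autosome label kept (29 for goat).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_snp_call_rate = 0.90, min_sample_call_rate = 0.90,
                      min_maf = 0.01, autosomes_only = TRUE,
                      n_autosomes = 29L) {
  stopifnot(min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  structure(list(min_snp_call_rate = min_snp_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 min_maf = min_maf, autosomes_only = autosomes_only,
                 n_autosomes = as.integer(n_autosomes)),
            class = "qc_config")
}

#' Apply genotype quality control
#'
#' Filters in a fixed, documented order: (1) drop non-autosomal/unmapped SNPs;
#' (2) drop samples below the sample call rate; (3) drop SNPs below the SNP
#' call rate (computed on surviving samples); (4) drop SNPs below the MAF
#' threshold (frequencies computed on surviving samples). No Hardy-Weinberg
#' filter is applied. The operation is idempotent.
#'
#' @param gm A [geno_matrix()].
#' @param cfg A [qc_config()].
#' @return The filtered `geno_matrix`, with a tibble report attached as
#'   attribute `"qc_report"` (step, items_removed, items_remaining), also
#'   retrievable with [qc_report()].
#' @export
apply_qc <- function(gm, cfg = qc_config()) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(cfg, "qc_config"))
  if (nrow(gm$samples) == 0 || nrow(gm$map) == 0) {
    stop("empty genotype matrix", call. = FALSE)
  }
  steps <- list()
  note <- function(step, unit, removed, remaining) {
    steps[[length(steps) + 1]] <<- tibble::tibble(
      step = step, unit = unit,
      items_removed = as.integer(removed),
      items_remaining = as.integer(remaining))
  }

  if (cfg$autosomes_only) {
    keep <- gm$map$chrom >= 1L & gm$map$chrom <= cfg$n_autosomes
    note("autosomes_only", "snp", sum(!keep), sum(keep))
    if (!all(keep)) gm <- subset_geno(gm, snps = keep)
  }
  if (nrow(gm$map) == 0) stop("all SNPs removed by QC", call. = FALSE)

  cr_sample <- rowMeans(!is.na(gm$calls))
  keep_s <- cr_sample >= cfg$min_sample_call_rate
  note("sample_call_rate", "sample", sum(!keep_s), sum(keep_s))
  if (!any(keep_s)) stop("all samples removed by QC", call. = FALSE)
  if (!all(keep_s)) gm <- subset_geno(gm, samples = keep_s)

  cr_snp <- colMeans(!is.na(gm$calls))
  keep_v <- cr_snp >= cfg$min_snp_call_rate
  note("snp_call_rate", "snp", sum(!keep_v), sum(keep_v))
  if (!any(keep_v)) stop("all SNPs removed by QC", call. = FALSE)
  if (!all(keep_v)) gm <- subset_geno(gm, snps = keep_v)

  af <- allele_frequencies(gm)
  keep_m <- !is.na(af$maf) & af$maf >= cfg$min_maf
  note("maf", "snp", sum(!keep_m), sum(keep_m))
  if (!any(keep_m)) stop("all SNPs removed by QC", call. = FALSE)
  if (!all(keep_m)) gm <- subset_geno(gm, snps = keep_m)

  attr(gm, "qc_report") <- dplyr::bind_rows(steps)
  gm
}

#' @rdname apply_qc
#' @export
qc_report <- function(gm) {
  rep <- attr(gm, "qc_report")
  if (is.null(rep)) {
    stop("no QC report attached; run apply_qc() first", call. = FALSE)
  }
  rep
}
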