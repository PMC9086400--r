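#' Parameters for consecutive-method run detection
#'
#' Defaults reproduce the standard SNP-chip parameterization for both run
#' types: at least 15 consecutive SNPs and 500 kb, with up to two missing
#' genotypes per run and up to one heterozygote inside an ROH (or up to three
#' homozygotes inside an ROHet) to absorb occasional genotyping errors. A gap
#' between adjacent SNPs larger than `max_gap_bp` (default 1 Mb, the usual
#' consecutive-method default) closes the run.
#'
#' @param run_type `"ROH"` (runs of homozygosity) or `"ROHET"` (runs of
#'   heterozygosity).
#' @param min_snps Minimum SNPs spanned by an emitted run.
#' @param min_length_bp Minimum run length in bp (endpoints inclusive).
#' @param max_opposite Maximum interior opposite-genotype calls allowed
#'   (heterozygotes in an ROH; homozygotes in an ROHet). Default 1 for ROH,
#'   3 for ROHET.
#' @param max_missing Maximum interior missing calls allowed.
#' @param max_gap_bp Maximum distance between adjacent SNPs inside a run.
#' @param conforming_only_min_snps If TRUE, test `min_snps` against the count
#'   of conforming SNPs only instead of all SNPs spanned.
#' @return A list of class `run_params`.
#' @export
run_params <- function(run_type = c("ROH", "ROHET"), min_snps = 15L,
                       min_length_bp = 500000, max_opposite = NULL,
                       max_missing = 2L, max_gap_bp = 1e6,
                       conforming_only_min_snps = FALSE) {
  run_type <- match.arg(run_type)
  if (is.null(max_opposite)) {
    max_opposite <- if (run_type == "ROH") 1L else 3L
  }
  stopifnot(min_snps >= 1, min_length_bp >= 0, max_opposite >= 0,
            max_missing >= 0, max_gap_bp > 0)
  structure(list(run_type = run_type, min_snps = as.integer(min_snps),
                 min_length_bp = as.numeric(min_length_bp),
                 max_opposite = as.integer(max_opposite),
                 max_missing = as.integer(max_missing),
                 max_gap_bp = as.numeric(max_gap_bp),
                 conforming_only_min_snps = isTRUE(conforming_only_min_snps)),
            class = "run_params")
}

# Per-chromosome scan for one sample. cat: 0 conforming, 1 opposite, 2 missing.
# A candidate starts on a conforming SNP and extends while interior allowance
# counters stay within bounds and adjacent-SNP gaps stay <= max_gap_bp. On a
# violation the candidate is trimmed to conforming endpoints and emitted if it
# meets the SNP-count and length minima. Scanning restarts after the violating
# SNP (at it, for a gap violation: the right-hand SNP is not itself faulty).
scan_chromosome <- function(cat, pos, p) {
  n <- length(cat)
  out <- vector("list", 8L)
  n_out <- 0L
  i <- 1L
  while (i <= n) {
    if (cat[i] != 0L) { i <- i + 1L; next }
    opp <- 0L; miss <- 0L
    k <- i + 1L
    gap_viol <- FALSE
    while (k <= n) {
      if (pos[k] - pos[k - 1L] > p$max_gap_bp) { gap_viol <- TRUE; break }
      ck <- cat[k]
      if (ck == 1L) {
        opp <- opp + 1L
        if (opp > p$max_opposite) break
      } else if (ck == 2L) {
        miss <- miss + 1L
        if (miss > p$max_missing) break
      }
      k <- k + 1L
    }
    end <- k - 1L
    while (end > i && cat[end] != 0L) end <- end - 1L
    span <- cat[i:end]
    n_span <- end - i + 1L
    n_for_min <- if (p$conforming_only_min_snps) sum(span == 0L) else n_span
    len <- pos[end] - pos[i] + 1
    if (n_for_min >= p$min_snps && len >= p$min_length_bp) {
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- c(i, end, sum(span == 1L), sum(span == 2L))
    }
    i <- if (k > n || gap_viol) k else k + 1L
  }
  if (n_out == 0L) return(NULL)
  do.call(rbind, out[seq_len(n_out)])
}

#' Detect runs of homozygosity or heterozygosity
#'
#' Scans each individual's genotypes chromosome by chromosome in map order
#' with the consecutive method: a candidate run grows while conforming
#' genotypes (homozygous for ROH, heterozygous for ROHet) accrue, tolerating
#' up to `max_opposite` interior opposite calls, `max_missing` interior
#' missing calls, and inter-SNP gaps up to `max_gap_bp`. When a constraint is
#' violated the candidate is trimmed so both endpoints are conforming calls
#' and emitted if it spans at least `min_snps` SNPs and `min_length_bp` bp;
#' scanning then restarts after the violating SNP. Runs of one individual
#' never overlap.
#'
#' @param gm A [geno_matrix()] (map must be position-sorted, which
#'   [geno_matrix()] guarantees).
#' @param params A [run_params()].
#' @return A tibble with one row per run: `sample_id`, `population`, `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive, at SNP positions), `n_snps`
#'   (all SNPs spanned), `n_opposite`, `n_missing`, `length_bp`
#'   (`end_bp - start_bp + 1`) and `run_type`.
#' @export
#' @examples
#' sim <- sim_cohort(sim_config(seed = 7))
#' roh <- detect_runs(sim$gm, run_params("ROH"))
#' head(roh)
detect_runs <- function(gm, params = run_params("ROH")) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(params, "run_params"))
  map <- gm$map
  if (is.unsorted(order(map$chrom, map$pos_bp))) {
    stop("marker map must be sorted by chrom, pos_bp", call. = FALSE)
  }
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(cc) which(map$chrom == cc))
  res <- vector("list", nrow(gm$samples) * length(chroms))
  r <- 0L
  for (s in seq_len(nrow(gm$samples))) {
    g <- gm$calls[s, ]
    cat_all <- if (params$run_type == "ROH") {
      ifelse(is.na(g), 2L, ifelse(g == 1L, 1L, 0L))
    } else {
      ifelse(is.na(g), 2L, ifelse(g == 1L, 0L, 1L))
    }
    for (ci in seq_along(chroms)) {
      idx <- chrom_idx[[ci]]
      m <- scan_chromosome(cat_all[idx], map$pos_bp[idx], params)
      if (is.null(m)) next
      r <- r + 1L
      res[[r]] <- tibble::tibble(
        sample_id = gm$samples$sample_id[s],
        population = gm$samples$population[s],
        chrom = chroms[ci],
        start_bp = map$pos_bp[idx[m[, 1]]],
        end_bp = map$pos_bp[idx[m[, 2]]],
        n_snps = m[, 2] - m[, 1] + 1L,
        n_opposite = m[, 3],
        n_missing = m[, 4])
    }
  }
  out <- if (r == 0L) {
    tibble::tibble(sample_id = character(), population = character(),
                   chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                   n_snps = integer(), n_opposite = integer(),
                   n_missing = integer())
  } else {
    dplyr::bind_rows(res[seq_len(r)])
  }
  out$length_bp <- out$end_bp - out$start_bp + 1
  out$run_type <- rep(params$run_type, nrow(out))
  out
}

#' Run length classes
#'
#' ROH lengths are classified into 0.5-2, 2-4, 4-8, 8-16 and >16 Mb; ROHet
#' lengths into 0.5-1, 1-1.5, 1.5-2 and >2 Mb. Bins are half-open
#' `[lo, hi)`, so a 2 Mb ROH falls in the 2-4 Mb class.
#'
#' @param run_type `"ROH"` or `"ROHET"`.
#' @return A tibble: `class_label`, `lo_bp`, `hi_bp`.
#' @export
run_length_classes <- function(run_type = c("ROH", "ROHET")) {
  run_type <- match.arg(run_type)
  if (run_type == "ROH") {
    tibble::tibble(
      class_label = c("0.5-2Mb", "2-4Mb", "4-8Mb", "8-16Mb", ">16Mb"),
      lo_bp = c(0.5, 2, 4, 8, 16) * 1e6,
      hi_bp = c(2, 4, 8, 16, Inf) * 1e6)
  } else {
    tibble::tibble(
      class_label = c("0.5-1Mb", "1-1.5Mb", "1.5-2Mb", ">2Mb"),
      lo_bp = c(0.5, 1, 1.5, 2) * 1e6,
      hi_bp = c(1, 1.5, 2, Inf) * 1e6)
  }
}

#' @rdname run_length_classes
#' @param length_bp Numeric vector of run lengths.
#' @return For `run_length_class()`: a factor of class labels (NA below the
#'   lowest boundary).
#' @export
run_length_class <- function(length_bp, run_type = c("ROH", "ROHET")) {
  cls <- run_length_classes(match.arg(run_type))
  cut(length_bp, breaks = c(cls$lo_bp, Inf)[!duplicated(c(cls$lo_bp, Inf))],
      labels = cls$class_label, right = FALSE)
}

#' Classify runs into length classes
#'
#' @param runs A run tibble from [detect_runs()].
#' @param run_type `"ROH"` or `"ROHET"`; defaults to the type of the runs.
#' @return A tibble with one row per class: `class_label`, `n_runs`,
#'   `total_length_bp` (zero-count classes included).
#' @export
classify_runs <- function(runs, run_type = NULL) {
  if (is.null(run_type)) {
    run_type <- if (nrow(runs)) runs$run_type[1] else "ROH"
  }
  if (nrow(runs) && !all(runs$run_type == run_type)) {
    stop("runs contain a mix of run types", call. = FALSE)
  }
  cls <- run_length_classes(run_type)
  lab <- run_length_class(runs$length_bp, run_type)
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " run(s) below the lowest class boundary dropped",
            call. = FALSE)
  }
  tibble::tibble(class_label = cls$class_label) %>%
    dplyr::left_join(
      tibble::tibble(class_label = as.character(lab),
                     length_bp = runs$length_bp) %>%
        dplyr::filter(!is.na(.data$class_label)) %>%
        dplyr::group_by(.data$class_label) %>%
        dplyr::summarise(n_runs = dplyr::n(),
                         total_length_bp = sum(.data$length_bp)),
      by = "class_label") %>%
    dplyr::mutate(n_runs = dplyr::coalesce(.data$n_runs, 0L),
                  total_length_bp = dplyr::coalesce(.data$total_length_bp, 0))
}

#' Summarize detected runs
#'
#' @param runs A run tibble from [detect_runs()] (one run type).
#' @param gm The [geno_matrix()] the runs were called from (supplies the full
#'   sample list so individuals with zero runs enter every denominator).
#' @param build A [genome_build()] giving per-chromosome lengths.
#' @return A list of class `runs_summary`:
#'   `per_sample` (count and total length per individual, zero-run
#'   individuals included), `per_population` (means, and the coefficient of
#'   variation of per-sample total length, `NA`-flagged for populations of
#'   size < 2), `per_chromosome` (mean percent of each chromosome covered by
#'   runs across all samples), and `count_length_cor` (Pearson r between
#'   per-sample run count and total length; undefined-flagged when degenerate).
#' @export
summarize_runs <- function(runs, gm, build) {
  stopifnot(inherits(gm, "geno_matrix"))
  base <- gm$samples[, c("sample_id", "population")]
  per_sample <- base %>%
    dplyr::left_join(
      runs %>% dplyr::group_by(.data$sample_id) %>%
        dplyr::summarise(n_runs = dplyr::n(),
                         total_length_bp = sum(.data$length_bp)),
      by = "sample_id") %>%
    dplyr::mutate(n_runs = dplyr::coalesce(.data$n_runs, 0L),
                  total_length_bp = dplyr::coalesce(.data$total_length_bp, 0),
                  total_mb = .data$total_length_bp / 1e6)

  per_population <- per_sample %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_n_runs = mean(.data$n_runs),
      mean_total_mb = mean(.data$total_mb),
      cv_total_length = ifelse(
        dplyr::n() < 2 || mean(.data$total_length_bp) == 0, NA_real_,
        stats::sd(.data$total_length_bp) / mean(.data$total_length_bp)),
      cv_undefined = dplyr::n() < 2)

  n_samp <- nrow(gm$samples)
  per_chromosome <- tibble::tibble(chrom = build$chrom,
                                   length_bp = build$length_bp) %>%
    dplyr::left_join(
      runs %>% dplyr::group_by(.data$chrom) %>%
        dplyr::summarise(run_bp = sum(.data$length_bp)),
      by = "chrom") %>%
    dplyr::mutate(
      run_bp = dplyr::coalesce(.data$run_bp, 0),
      coverage_pct = 100 * .data$run_bp / (.data$length_bp * n_samp)) %>%
    dplyr::select("chrom", "length_bp", "coverage_pct")

  cl_cor <- correlate(per_sample$n_runs, per_sample$total_length_bp)
  structure(list(per_sample = per_sample, per_population = per_population,
                 per_chromosome = per_chromosome, count_length_cor = cl_cor),
            class = "runs_summary")
}

#' Export runs as BED intervals
#'
#' Converts 1-based inclusive run coordinates to 0-based half-open BED.
#'
#' @param runs A run tibble.
#' @param path Optional output path; when given, a headerless 4-column BED
#'   (chrom, start, end, sample) is written.
#' @return A tibble with BED-convention `start`/`end`, invisibly when written.
#' @export
runs_to_bed <- function(runs, path = NULL) {
  bed <- tibble::tibble(chrom = runs$chrom,
                        start = runs$start_bp - 1,
                        end = runs$end_bp,
                        name = runs$sample_id)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
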