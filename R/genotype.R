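#' Genotype container for SNP-array data
#'
#' A `geno_matrix` bundles a sample table, a marker map and an integer call
#' matrix. Calls are coded 0 (homozygous for the A allele), 1 (heterozygous),
#' 2 (homozygous for the B allele) and `NA` (missing). The map is kept sorted
#' by chromosome and physical position; every downstream operation relies on
#' that ordering.
#'
#' @param calls Integer matrix, samples in rows and SNPs in columns, values in
#'   `{0, 1, 2, NA}`. Row names are taken as sample ids and column names as
#'   SNP ids when `samples`/`map` do not supply them.
#' @param samples Data frame with columns `sample_id` and `population`.
#' @param map Data frame with columns `snp_id`, `chrom` (integer autosome
#'   label), `pos_bp` (1-based physical position), and optionally `allele_a`,
#'   `allele_b` (base symbols backing codes 0 and 2).
#'
#' @return An object of class `geno_matrix`: a list with elements `samples`
#'   (tibble), `map` (tibble) and `calls` (integer matrix).
#' @export
#' @examples
#' gm <- geno_matrix(
#'   calls = rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'   samples = data.frame(sample_id = c("s1", "s2"), population = "pop1"),
#'   map = data.frame(snp_id = c("m1", "m2"), chrom = 1L, pos_bp = c(100L, 200L))
#' )
#' gm
geno_matrix <- function(calls, samples, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- tibble::as_tibble(samples)
  map <- tibble::as_tibble(map)
  if (!all(c("sample_id", "population") %in% names(samples))) {
    stop("`samples` needs columns sample_id and population", call. = FALSE)
  }
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(map))) {
    stop("`map` needs columns snp_id, chrom and pos_bp", call. = FALSE)
  }
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(map)) {
    stop("`calls` must be samples x SNPs (", nrow(samples), " x ", nrow(map),
         "), got ", nrow(calls), " x ", ncol(calls), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id", call. = FALSE)
  }
  if (anyDuplicated(map$snp_id)) {
    stop("duplicated snp_id", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(calls)), c(0L, 1L, 2L, NA_integer_))
  if (length(bad)) {
    stop("calls contain codes outside {0, 1, 2, NA}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(map$pos_bp < 1)) stop("pos_bp must be >= 1", call. = FALSE)
  map$chrom <- as.integer(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  ord <- order(map$chrom, map$pos_bp)
  if (!identical(ord, seq_along(ord))) {
    warning("marker map not sorted by (chrom, pos_bp); sorting", call. = FALSE)
    map <- map[ord, ]
    calls <- calls[, ord, drop = FALSE]
  }
  dup_pos <- duplicated(map[, c("chrom", "pos_bp")])
  if (any(dup_pos)) {
    stop("positions within a chromosome must be strictly increasing; ",
         "duplicated position at ", map$snp_id[which(dup_pos)[1]], call. = FALSE)
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- map$snp_id
  structure(list(samples = samples, map = map, calls = calls),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$samples), " samples x ", nrow(x$map), " SNPs\n",
      sep = "")
  cat("  populations: ",
      paste(utils::head(unique(x$samples$population), 5), collapse = ", "),
      if (length(unique(x$samples$population)) > 5) ", ..." else "", "\n",
      sep = "")
  cat("  chromosomes: ", length(unique(x$map$chrom)),
      "; missing rate: ",
      signif(mean(is.na(x$calls)), 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$samples), nrow(x$map))

#' One-row summary of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A one-row tibble: sample count, SNP count, chromosome count,
#'   population count and overall missing-call rate.
#' @method glance geno_matrix
#' @export
glance.geno_matrix <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_snps = nrow(x$map),
    n_chrom = length(unique(x$map$chrom)),
    n_populations = length(unique(x$samples$population)),
    missing_rate = mean(is.na(x$calls))
  )
}

#' Subset a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @param samples Logical/integer/character index into samples (default all).
#' @param snps Logical/integer/character index into SNPs (default all).
#' @return A `geno_matrix` restricted to the selected rows and columns.
#' @export
subset_geno <- function(gm, samples = NULL, snps = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(gm$samples)) else samples
  if (is.character(si)) si <- match(si, gm$samples$sample_id)
  vi <- if (is.null(snps)) seq_len(nrow(gm$map)) else snps
  if (is.character(vi)) vi <- match(vi, gm$map$snp_id)
  geno_matrix(gm$calls[si, vi, drop = FALSE],
              gm$samples[si, , drop = FALSE],
              gm$map[vi, , drop = FALSE])
}

#' Per-SNP allele frequencies
#'
#' Computes the frequency of the B allele (code 2) at every SNP as
#' `(2 n_homB + n_het) / (2 n_nonmissing)`. SNPs with no non-missing call are
#' flagged undefined (`NA` frequency).
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, `pos_bp`,
#'   `n_called` (non-missing genotypes), `freq_b`, `maf`, and `undefined`
#'   (TRUE where no genotype was observed).
#' @export
#' @examples
#' gm <- sim_cohort(sim_config(n_chrom = 1, chrom_length_bp = 2e6, seed = 1))$gm
#' allele_frequencies(gm)
allele_frequencies <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  cl <- gm$calls
  n_called <- unname(colSums(!is.na(cl)))
  b_dose <- unname(colSums(cl, na.rm = TRUE))
  freq <- ifelse(n_called > 0, b_dose / (2 * n_called), NA_real_)
  tibble::tibble(
    snp_id = gm$map$snp_id,
    chrom = gm$map$chrom,
    pos_bp = gm$map$pos_bp,
    n_called = as.integer(n_called),
    freq_b = freq,
    maf = pmin(freq, 1 - freq),
    undefined = n_called == 0
  )
}

#' Describe an autosome set
#'
#' Holds per-chromosome lengths and their total, the denominator of F_ROH and
#' of the ROH-class genome fractions (the autosomal genome length L_g).
#'
#' @param chrom_lengths_bp Named or unnamed numeric vector of per-autosome
#'   lengths in bp; names default to 1..k.
#' @return A `genome_build`: tibble with `chrom` and `length_bp`, plus a
#'   `total_autosome_bp` attribute.
#' @export
#' @examples
#' gb <- genome_build(c(`1` = 1.5e8, `2` = 1.2e8))
#' total_autosome_bp(gb)
genome_build <- function(chrom_lengths_bp) {
  stopifnot(all(chrom_lengths_bp > 0))
  chrom <- if (is.null(names(chrom_lengths_bp))) {
    seq_along(chrom_lengths_bp)
  } else {
    as.integer(names(chrom_lengths_bp))
  }
  out <- tibble::tibble(chrom = as.integer(chrom),
                        length_bp = as.numeric(chrom_lengths_bp))
  attr(out, "total_autosome_bp") <- sum(out$length_bp)
  class(out) <- c("genome_build", class(out))
  out
}

#' @rdname genome_build
#' @param build A `genome_build` (or a single number, passed through).
#' @export
total_autosome_bp <- function(build) {
  if (is.numeric(build) && length(build) == 1) return(as.numeric(build))
  stopifnot(inherits(build, "genome_build"))
  attr(build, "total_autosome_bp")
}

#' @rdname genome_build
#' @param map A marker map (tibble with `chrom`, `pos_bp`); lengths are taken
#'   as the last mapped position per chromosome.
#' @export
genome_build_from_map <- function(map) {
  len <- tapply(map$pos_bp, map$chrom, max)
  genome_build(stats::setNames(as.numeric(len), names(len)))
}
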