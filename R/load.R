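#' Polarize panel alleles against a wild outgroup
#'
#' Infers the ancestral state of each SNP as the allele with frequency
#' greater than 0.5 in the outgroup (the major homozygous state of the wild
#' population). Frequency exactly 0.5, or an outgroup with no call at the
#' SNP, leaves the site UNPOLARIZED; unpolarized sites are excluded from all
#' load and damaging-homozygote counts downstream.
#'
#' @param gm The study panel [geno_matrix()] (supplies the SNP ids and, when
#'   present, allele symbols for alignment).
#' @param outgroup Either a [geno_matrix()] of outgroup individuals or a
#'   tibble with `snp_id` and `freq_b` (frequency, in the outgroup, of the
#'   panel's B allele).
#' @return A tibble: `snp_id`, `outgroup_freq_b`, `ancestral` ("A", "B" or
#'   "UNPOLARIZED").
#' @export
polarize_ancestral <- function(gm, outgroup) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (inherits(outgroup, "geno_matrix")) {
    og <- allele_frequencies(outgroup)[, c("snp_id", "freq_b")]
    if (all(c("allele_a", "allele_b") %in% names(gm$map)) &&
        all(c("allele_a", "allele_b") %in% names(outgroup$map))) {
      al <- dplyr::inner_join(
        gm$map[, c("snp_id", "allele_a", "allele_b")],
        outgroup$map[, c("snp_id", "allele_a", "allele_b")],
        by = "snp_id", suffix = c("", "_og"))
      swapped <- al$snp_id[al$allele_a == al$allele_b_og &
                             al$allele_b == al$allele_a_og &
                             al$allele_a != al$allele_b]
      og$freq_b[og$snp_id %in% swapped] <-
        1 - og$freq_b[og$snp_id %in% swapped]
    }
  } else {
    og <- tibble::as_tibble(outgroup)
    stopifnot(all(c("snp_id", "freq_b") %in% names(og)))
  }
  tab <- dplyr::left_join(gm$map[, "snp_id", drop = FALSE], og, by = "snp_id")
  if (!any(!is.na(tab$freq_b))) {
    stop("no overlapping SNPs between panel and outgroup", call. = FALSE)
  }
  tibble::tibble(
    snp_id = tab$snp_id,
    outgroup_freq_b = tab$freq_b,
    ancestral = dplyr::case_when(
      is.na(tab$freq_b) ~ "UNPOLARIZED",
      tab$freq_b > 0.5 ~ "B",
      tab$freq_b < 0.5 ~ "A",
      TRUE ~ "UNPOLARIZED"))
}

# Collapse multi-consequence annotations by severity.
severity_rank <- c(LOF = 1, MISSENSE = 2, SYNONYMOUS = 3, OTHER = 4)

#' Flag deleterious, tolerated and damaging variants
#'
#' Missense SNPs with a SIFT score at or below `sift_threshold` (inclusive,
#' default 0.05) are deleterious; missense above it are tolerated; damaging
#' is the union of deleterious and loss-of-function. SNPs listed with several
#' consequences are collapsed to the most severe
#' (LOF > MISSENSE > SYNONYMOUS > OTHER) before flagging.
#'
#' @param ann Tibble with `snp_id`, `consequence` (SYNONYMOUS, MISSENSE, LOF
#'   or OTHER) and `sift_score` (only meaningful for MISSENSE).
#' @param sift_threshold SIFT cutoff, inclusive.
#' @return `ann` (one row per SNP) with logical columns `deleterious`,
#'   `tolerated`, `damaging`.
#' @export
classify_deleterious <- function(ann, sift_threshold = 0.05) {
  ann <- tibble::as_tibble(ann)
  if (anyDuplicated(ann$snp_id)) {
    ann <- ann %>%
      dplyr::mutate(.rank = severity_rank[.data$consequence]) %>%
      dplyr::group_by(.data$snp_id) %>%
      dplyr::slice_min(.data$.rank, n = 1, with_ties = FALSE) %>%
      dplyr::ungroup() %>%
      dplyr::select(-".rank")
  }
  ann %>% dplyr::mutate(
    deleterious = .data$consequence == "MISSENSE" &
      !is.na(.data$sift_score) & .data$sift_score <= sift_threshold,
    tolerated = .data$consequence == "MISSENSE" &
      !is.na(.data$sift_score) & .data$sift_score > sift_threshold,
    damaging = .data$deleterious | .data$consequence == "LOF")
}

# Per-sample counts of heterozygous and derived-homozygous calls over a SNP
# index set. anc_b: logical, ancestral allele is B (derived hom = code 0).
count_derived <- function(calls, idx, anc_b) {
  if (!length(idx)) {
    z <- integer(nrow(calls))
    return(list(het = z, hom = z))
  }
  sub <- calls[, idx, drop = FALSE]
  hom_mat <- sweep(sub, 2, ifelse(anc_b[idx], 0L, 2L), `==`)
  list(het = unname(rowSums(sub == 1L, na.rm = TRUE)),
       hom = unname(rowSums(hom_mat, na.rm = TRUE)))
}

#' Genetic load from deleterious and synonymous counts
#'
#' For every individual, counts heterozygous and derived-homozygous genotypes
#' at polarized deleterious and synonymous sites and forms the load ratios
#' `load_het = n_del_het / n_syn_het`,
#' `load_hom = n_del_hom / n_syn_hom`, and the allele-dosage-weighted
#' `load_total = (n_del_het + 2 n_del_hom) / (n_syn_het + 2 n_syn_hom)`.
#' Unpolarized sites are excluded throughout; zero denominators flag the
#' ratio undefined (`NA`).
#'
#' @param gm A [geno_matrix()].
#' @param ann Annotation tibble (run through [classify_deleterious()] if the
#'   flag columns are absent).
#' @param ancestral Output of [polarize_ancestral()].
#' @param numerator `"deleterious"` (SIFT-based, default) or `"damaging"`
#'   (deleterious plus LOF) for the numerator site set.
#' @param sift_threshold Passed to [classify_deleterious()] when needed.
#' @return A list: `per_sample` (counts, ratios and undefined flags) and
#'   `per_population` (means of the defined ratios).
#' @export
genetic_load <- function(gm, ann, ancestral, numerator = c("deleterious",
                                                           "damaging"),
                         sift_threshold = 0.05) {
  numerator <- match.arg(numerator)
  stopifnot(inherits(gm, "geno_matrix"))
  if (!all(c("deleterious", "damaging") %in% names(ann))) {
    ann <- classify_deleterious(ann, sift_threshold)
  }
  tab <- gm$map[, "snp_id", drop = FALSE] %>%
    dplyr::left_join(ann, by = "snp_id") %>%
    dplyr::left_join(ancestral, by = "snp_id")
  polarized <- !is.na(tab$ancestral) & tab$ancestral %in% c("A", "B")
  anc_b <- tab$ancestral == "B"
  num_idx <- which(polarized & dplyr::coalesce(tab[[numerator]], FALSE))
  syn_idx <- which(polarized &
                     dplyr::coalesce(tab$consequence == "SYNONYMOUS", FALSE))

  del <- count_derived(gm$calls, num_idx, anc_b)
  syn <- count_derived(gm$calls, syn_idx, anc_b)
  per_sample <- tibble::tibble(
    sample_id = gm$samples$sample_id,
    population = gm$samples$population,
    n_del_het = del$het, n_del_hom = del$hom,
    n_syn_het = syn$het, n_syn_hom = syn$hom) %>%
    dplyr::mutate(
      load_het = ifelse(.data$n_syn_het > 0,
                        .data$n_del_het / .data$n_syn_het, NA_real_),
      load_hom = ifelse(.data$n_syn_hom > 0,
                        .data$n_del_hom / .data$n_syn_hom, NA_real_),
      load_total = ifelse(.data$n_syn_het + 2 * .data$n_syn_hom > 0,
                          (.data$n_del_het + 2 * .data$n_del_hom) /
                            (.data$n_syn_het + 2 * .data$n_syn_hom),
                          NA_real_),
      undefined = is.na(.data$load_total))
  per_population <- per_sample %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(dplyr::across(c("load_het", "load_hom", "load_total"),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_samples = dplyr::n())
  list(per_sample = per_sample, per_population = per_population)
}

#' Enrichment of damaging homozygotes inside ROH classes
#'
#' Splits each individual's ROH into medium (A: 0.5-4 Mb) and long (B: >= 4
#' Mb) classes, computes the genome fraction `G_ij = L_ij / L_g` covered by
#' class j (R = A union B; N = outside all ROH, so `G_iA + G_iB = G_iR` and
#' `G_iR + G_iN = 1`), assigns every damaging derived homozygote to A, B or N
#' by positional containment (run endpoints inclusive), and correlates the
#' per-class fraction of an individual's damaging homozygotes with its
#' per-class genome coverage across individuals.
#'
#' @param runs ROH tibble from [detect_runs()].
#' @param gm A [geno_matrix()].
#' @param ann Annotation tibble (flags added if absent).
#' @param ancestral Output of [polarize_ancestral()].
#' @param build A [genome_build()] or total autosome length (L_g).
#' @param sift_threshold Passed to [classify_deleterious()] when needed.
#' @return A list: `per_sample` (long tibble: sample, class, `L_bp`, `G`,
#'   `n_damaging`, `damaging_fraction`) and `correlations` (Pearson r of
#'   damaging fraction against G per class).
#' @export
damaging_in_roh <- function(runs, gm, ann, ancestral, build,
                            sift_threshold = 0.05) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(runs) && !all(runs$run_type == "ROH")) {
    stop("damaging_in_roh() expects ROH-type runs", call. = FALSE)
  }
  if (!all(c("deleterious", "damaging") %in% names(ann))) {
    ann <- classify_deleterious(ann, sift_threshold)
  }
  L_g <- total_autosome_bp(build)
  tab <- gm$map %>%
    dplyr::left_join(ann[, c("snp_id", "damaging")], by = "snp_id") %>%
    dplyr::left_join(ancestral[, c("snp_id", "ancestral")], by = "snp_id")
  dmg_idx <- which(dplyr::coalesce(tab$damaging, FALSE) &
                     tab$ancestral %in% c("A", "B"))
  anc_b <- tab$ancestral == "B"

  runs <- runs %>%
    dplyr::mutate(roh_class = ifelse(.data$length_bp >= 4e6, "B",
                                     ifelse(.data$length_bp >= 5e5, "A",
                                            NA_character_)))
  # runs of one individual must not overlap
  chk <- runs %>% dplyr::arrange(.data$sample_id, .data$chrom, .data$start_bp)
  same <- chk$sample_id[-1] == chk$sample_id[-nrow(chk)] &
    chk$chrom[-1] == chk$chrom[-nrow(chk)]
  if (nrow(chk) > 1 && any(same & chk$start_bp[-1] <= chk$end_bp[-nrow(chk)])) {
    stop("overlapping runs within an individual", call. = FALSE)
  }

  per_sample <- purrr::map_dfr(seq_len(nrow(gm$samples)), function(s) {
    sid <- gm$samples$sample_id[s]
    rr <- runs[runs$sample_id == sid & !is.na(runs$roh_class), ]
    L_A <- sum(rr$length_bp[rr$roh_class == "A"])
    L_B <- sum(rr$length_bp[rr$roh_class == "B"])
    g <- gm$calls[s, dmg_idx]
    is_hom_derived <- !is.na(g) & g == ifelse(anc_b[dmg_idx], 0L, 2L)
    hit_idx <- dmg_idx[is_hom_derived]
    cls <- rep("N", length(hit_idx))
    if (length(hit_idx) && nrow(rr)) {
      for (h in seq_along(hit_idx)) {
        cc <- gm$map$chrom[hit_idx[h]]
        pp <- gm$map$pos_bp[hit_idx[h]]
        inside <- rr$chrom == cc & rr$start_bp <= pp & rr$end_bp >= pp
        if (any(inside)) cls[h] <- rr$roh_class[which(inside)[1]]
      }
    }
    n_tot <- length(hit_idx)
    counts <- c(A = sum(cls == "A"), B = sum(cls == "B"),
                R = sum(cls != "N"), N = sum(cls == "N"))
    L <- c(A = L_A, B = L_B, R = L_A + L_B, N = L_g - L_A - L_B)
    tibble::tibble(sample_id = sid, population = gm$samples$population[s],
                   roh_class = names(L), L_bp = unname(L),
                   G = unname(L) / L_g,
                   n_damaging = unname(counts),
                   damaging_fraction = if (n_tot > 0) {
                     unname(counts) / n_tot
                   } else {
                     NA_real_
                   })
  })

  correlations <- per_sample %>%
    dplyr::group_by(.data$roh_class) %>%
    dplyr::group_modify(~ correlate(.x$damaging_fraction, .x$G)) %>%
    dplyr::ungroup()
  list(per_sample = per_sample, correlations = correlations)
}
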