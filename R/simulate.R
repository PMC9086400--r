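#' Configuration for the synthetic SNP-chip cohort generator
#'
#' The generator emulates a medium-density (50K-like) autosomal SNP panel:
#' evenly spaced biallelic markers, founder haplotypes drawn independently
#' per SNP (no background linkage disequilibrium) except inside declared
#' balanced regions, gene dropping through an arbitrary pedigree with Haldane
#' (no-interference) crossovers at 1 cM/Mb, genotyping noise, a consequence
#' annotation layer, and a small wild outgroup for allele polarization. The
#' desk-scale default is 2 chromosomes of 50 Mb at 25 kb spacing (4,000
#' SNPs), dense enough that autozygous tracts above 0.5 Mb are well covered.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length_bp Length of each autosome in bp.
#' @param snp_spacing_bp Distance between adjacent SNPs in bp.
#' @param founder_count Number of founder individuals in the haplotype pool
#'   (2 haplotypes each); pedigree founders draw from this pool.
#' @param freq_range Range of the uniform founder B-allele frequency draw.
#' @param recomb_rate_cM_per_Mb Map scale; 1 cM/Mb by default so the
#'   generation-dating expectation L = 100/(2g) Mb applies directly.
#' @param genotype_missing_rate,genotype_error_rate Per-call rates in \[0,1\].
#' @param balanced_regions Tibble (`chrom`, `start_bp`, `end_bp`,
#'   `equilibrium_freq`) of regions where founder haplotypes are drawn from
#'   two divergent allelic classes held at the equilibrium frequency,
#'   producing excess intermediate-frequency variants and heterozygous
#'   clusters (a long-term balancing-selection signature). Regions must not
#'   overlap.
#' @param annotation_spec List: `p_synonymous`, `p_missense`, `p_lof`
#'   (per-SNP class proportions; the rest are OTHER) and
#'   `deleterious_fraction` (fraction of missense with SIFT below 0.05).
#' @param deleterious_placement `"uniform"` or
#'   `"enriched_in_recent_haplotypes"` (damaging labels preferentially on
#'   SNPs whose derived homozygotes fall inside long true IBD tracts).
#' @param outgroup_n Outgroup (wild ancestor) sample size; 24 emulates a
#'   typical bezoar panel.
#' @param seed Integer; fixes all randomness of the generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_length_bp = 50e6,
                       snp_spacing_bp = 25000,
                       founder_count = 50L,
                       freq_range = c(0.05, 0.95),
                       recomb_rate_cM_per_Mb = 1,
                       genotype_missing_rate = 0,
                       genotype_error_rate = 0,
                       balanced_regions = NULL,
                       annotation_spec = list(p_synonymous = 0.10,
                                              p_missense = 0.06,
                                              p_lof = 0.005,
                                              deleterious_fraction = 0.30),
                       deleterious_placement = c("uniform",
                                                 "enriched_in_recent_haplotypes"),
                       outgroup_n = 24L,
                       seed = 1L) {
  deleterious_placement <- match.arg(deleterious_placement)
  stopifnot(snp_spacing_bp > 0, chrom_length_bp > snp_spacing_bp,
            genotype_missing_rate >= 0, genotype_missing_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            length(freq_range) == 2, freq_range[1] > 0, freq_range[2] < 1)
  if (!is.null(balanced_regions)) {
    balanced_regions <- tibble::as_tibble(balanced_regions)
    br <- balanced_regions[order(balanced_regions$chrom,
                                 balanced_regions$start_bp), ]
    same <- which(diff(br$chrom) == 0)
    if (any(br$end_bp[same] >= br$start_bp[same + 1])) {
      stop("balanced regions overlap", call. = FALSE)
    }
  }
  structure(list(
    n_chrom = as.integer(n_chrom), chrom_length_bp = chrom_length_bp,
    snp_spacing_bp = snp_spacing_bp, founder_count = as.integer(founder_count),
    freq_range = freq_range, recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
    genotype_missing_rate = genotype_missing_rate,
    genotype_error_rate = genotype_error_rate,
    balanced_regions = balanced_regions, annotation_spec = annotation_spec,
    deleterious_placement = deleterious_placement,
    outgroup_n = as.integer(outgroup_n), seed = as.integer(seed)),
    class = "sim_config")
}

sim_map <- function(cfg) {
  pos <- seq(cfg$snp_spacing_bp, cfg$chrom_length_bp, by = cfg$snp_spacing_bp)
  tibble::tibble(
    chrom = rep(seq_len(cfg$n_chrom), each = length(pos)),
    pos_bp = rep(pos, cfg$n_chrom)) %>%
    dplyr::mutate(snp_id = sprintf("snp%d_%d", .data$chrom, .data$pos_bp),
                  allele_a = "A", allele_b = "B", .before = 1) %>%
    dplyr::select("snp_id", "chrom", "pos_bp", "allele_a", "allele_b")
}

#' Simulate a founder haplotype pool
#'
#' Draws per-SNP B-allele frequencies uniformly from `cfg$freq_range` and
#' founder haplotypes independently per SNP; the true ancestral allele of
#' each SNP is the major allele of the founding frequency (random side at
#' exactly 0.5). Inside each balanced region, two divergent allelic class
#' patterns are built (B-allele probabilities 0.9 and 0.1 per SNP) and every
#' haplotype adopts class 1 with probability `equilibrium_freq` (2% per-SNP
#' flip noise), which maintains intermediate frequencies and long-range
#' within-region haplotype structure.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `founder_pool`: `map`, `haps` (2 x founder_count
#'   rows of 0/1 B-allele indicators), `ancestral` ("A"/"B" per SNP),
#'   `founder_freq_b`, and `balanced_regions`.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    map <- sim_map(cfg)
    n_snp <- nrow(map)
    n_hap <- 2L * cfg$founder_count
    freq_b <- stats::runif(n_snp, cfg$freq_range[1], cfg$freq_range[2])
    haps <- matrix(stats::rbinom(n_hap * n_snp, 1L,
                                 rep(freq_b, each = n_hap)),
                   nrow = n_hap, ncol = n_snp)
    if (!is.null(cfg$balanced_regions)) {
      for (r in seq_len(nrow(cfg$balanced_regions))) {
        reg <- cfg$balanced_regions[r, ]
        idx <- which(map$chrom == reg$chrom & map$pos_bp >= reg$start_bp &
                       map$pos_bp <= reg$end_bp)
        if (!length(idx)) next
        pat1 <- stats::rbinom(length(idx), 1L, 0.9)
        pat2 <- stats::rbinom(length(idx), 1L, 0.1)
        cls1 <- stats::rbinom(n_hap, 1L, reg$equilibrium_freq) == 1L
        block <- matrix(rep(pat2, each = n_hap), nrow = n_hap)
        block[cls1, ] <- matrix(rep(pat1, each = sum(cls1)), nrow = sum(cls1))
        flip <- matrix(stats::rbinom(n_hap * length(idx), 1L, 0.02),
                       nrow = n_hap) == 1L
        block[flip] <- 1L - block[flip]
        haps[, idx] <- block
        freq_b[idx] <- reg$equilibrium_freq * 0.9 +
          (1 - reg$equilibrium_freq) * 0.1
      }
    }
    anc <- ifelse(freq_b > 0.5, "B", ifelse(freq_b < 0.5, "A",
                  ifelse(stats::runif(n_snp) < 0.5, "A", "B")))
    structure(list(map = map, haps = haps, ancestral = anc,
                   founder_freq_b = freq_b,
                   balanced_regions = cfg$balanced_regions),
              class = "founder_pool")
  })
}

# -- pedigree builders ------------------------------------------------------

#' Pedigree builders for the simulator
#'
#' Pedigrees are tibbles with columns `id`, `sire`, `dam` (NA for founders),
#' `population` and `focal` (the individuals meant to be analyzed). Parents
#' must appear before their offspring.
#'
#' @param n,n_families Number of individuals / independent families.
#' @param population Population label.
#' @return A pedigree tibble.
#' @export
ped_founders <- function(n, population = "sim") {
  tibble::tibble(id = sprintf("%s_F%d", population, seq_len(n)),
                 sire = NA_character_, dam = NA_character_,
                 population = population, focal = TRUE)
}

#' @rdname ped_founders
#' @details `ped_full_sib_families()`: each family mates two founders, then
#'   mates two of their children; the focal offspring has pedigree F = 0.25.
#' @export
ped_full_sib_families <- function(n_families, population = "fullsib") {
  purrr::map_dfr(seq_len(n_families), function(f) {
    p <- function(x) sprintf("%s%d_%s", population, f, x)
    tibble::tibble(
      id = p(c("A", "B", "S1", "S2", "O")),
      sire = c(NA, NA, p("A"), p("A"), p("S1")),
      dam = c(NA, NA, p("B"), p("B"), p("S2")),
      population = population,
      focal = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  })
}

#' @rdname ped_founders
#' @details `ped_first_cousin_families()`: full sibs marry unrelated
#'   spouses; their children (first cousins) mate; the focal offspring has
#'   pedigree F = 0.0625.
#' @export
ped_first_cousin_families <- function(n_families, population = "cousin") {
  purrr::map_dfr(seq_len(n_families), function(f) {
    p <- function(x) sprintf("%s%d_%s", population, f, x)
    tibble::tibble(
      id = p(c("G1", "G2", "S1", "S2", "C1", "C2", "K1", "K2", "O")),
      sire = c(NA, NA, NA, NA, p("G1"), p("G1"), p("C1"), p("C2"), p("K1")),
      dam = c(NA, NA, NA, NA, p("G2"), p("G2"), p("S1"), p("S2"), p("K2")),
      population = population,
      focal = c(rep(FALSE, 8), TRUE))
  })
}

#' @rdname ped_founders
#' @details `ped_outbred_families()`: each focal offspring is the child of
#'   two unrelated founders (pedigree F = 0).
#' @export
ped_outbred_families <- function(n_families, population = "outbred") {
  purrr::map_dfr(seq_len(n_families), function(f) {
    p <- function(x) sprintf("%s%d_%s", population, f, x)
    tibble::tibble(
      id = p(c("A", "B", "O")),
      sire = c(NA, NA, p("A")), dam = c(NA, NA, p("B")),
      population = population, focal = c(FALSE, FALSE, TRUE))
  })
}

# Numerator-relationship diagonal via the tabular method; F = A_ii - 1.
pedigree_f <- function(pedigree) {
  n <- nrow(pedigree)
  idx <- stats::setNames(seq_len(n), pedigree$id)
  s <- idx[pedigree$sire]
  d <- idx[pedigree$dam]
  if (any(xor(is.na(s), is.na(d)))) {
    stop("individuals must have zero or two parents", call. = FALSE)
  }
  if (any(stats::na.omit(c(s, d) - rep(seq_len(n), 2)) >= 0)) {
    stop("pedigree must list parents before offspring", call. = FALSE)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (is.na(s[i])) {
      A[i, i] <- 1
    } else {
      if (i > 1) {
        j <- seq_len(i - 1L)
        A[i, j] <- 0.5 * (A[s[i], j] + A[d[i], j])
        A[j, i] <- A[i, j]
      }
      A[i, i] <- 1 + 0.5 * A[s[i], d[i]]
    }
  }
  tibble::tibble(sample_id = pedigree$id, F_ped = diag(A) - 1)
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Transmits pool haplotypes through the pedigree with Haldane crossovers:
#' per meiosis and chromosome, the crossover count is Poisson with mean
#' `chrom_length_Mb * recomb_rate / 100` and breakpoints are uniform.
#' Founder-haplotype descent labels are tracked alongside alleles, so each
#' individual's autozygous (identity-by-descent) tracts are recorded exactly
#' as the maximal runs of SNPs whose two labels agree. Pedigree inbreeding
#' coefficients are computed by the tabular (path-counting) method.
#'
#' @param founders A [simulate_founders()] pool.
#' @param pedigree A pedigree tibble (see [ped_founders()]); its founders are
#'   assigned pool individuals in order, so the pool must hold at least as
#'   many founders as the pedigree.
#' @param cfg The [sim_config()] used for the pool.
#' @return A list of class `sim_drop`: `gm` (a [geno_matrix()] of every
#'   pedigree individual, noise-free), `truth` (list with `tracts`,
#'   `pedigree_f`, `ancestral`), and `pedigree`.
#' @export
gene_drop <- function(founders, pedigree, cfg) {
  stopifnot(inherits(founders, "founder_pool"), inherits(cfg, "sim_config"))
  pedigree <- tibble::as_tibble(pedigree)
  map <- founders$map
  n_snp <- nrow(map)
  n_ind <- nrow(pedigree)
  is_founder <- is.na(pedigree$sire)
  n_found <- sum(is_founder)
  if (n_found > cfg$founder_count) {
    stop("pedigree needs ", n_found, " founders but the pool holds ",
         cfg$founder_count, call. = FALSE)
  }
  if (any(xor(is.na(pedigree$sire), is.na(pedigree$dam)))) {
    stop("individuals must have zero or two parents", call. = FALSE)
  }
  chrom_idx <- split(seq_len(n_snp), map$chrom)
  chrom_len <- cfg$chrom_length_bp
  xo_mean <- (chrom_len / 1e6) * cfg$recomb_rate_cM_per_Mb / 100

  withr::with_seed(cfg$seed + 1L, {
    H1 <- matrix(0L, n_ind, n_snp); H2 <- matrix(0L, n_ind, n_snp)
    L1 <- matrix(0L, n_ind, n_snp); L2 <- matrix(0L, n_ind, n_snp)
    idx_of <- stats::setNames(seq_len(n_ind), pedigree$id)
    f_counter <- 0L
    gamete <- function(par) {
      g_allele <- integer(n_snp); g_label <- integer(n_snp)
      for (ci in chrom_idx) {
        k <- stats::rpois(1, xo_mean)
        pos <- map$pos_bp[ci]
        breaks <- sort(stats::runif(k, 0, chrom_len))
        seg <- findInterval(pos, breaks)  # 0..k
        start_hap <- stats::rbinom(1, 1, 0.5)
        use1 <- (seg + start_hap) %% 2 == 0
        g_allele[ci] <- ifelse(use1, H1[par, ci], H2[par, ci])
        g_label[ci] <- ifelse(use1, L1[par, ci], L2[par, ci])
      }
      list(a = g_allele, l = g_label)
    }
    for (i in seq_len(n_ind)) {
      if (is_founder[i]) {
        f_counter <- f_counter + 1L
        h <- 2L * f_counter
        H1[i, ] <- founders$haps[h - 1L, ]; H2[i, ] <- founders$haps[h, ]
        L1[i, ] <- h - 1L; L2[i, ] <- h
      } else {
        gs <- gamete(idx_of[[pedigree$sire[i]]])
        gd <- gamete(idx_of[[pedigree$dam[i]]])
        H1[i, ] <- gs$a; H2[i, ] <- gd$a
        L1[i, ] <- gs$l; L2[i, ] <- gd$l
      }
    }
  })

  calls <- H1 + H2
  samples <- tibble::tibble(sample_id = pedigree$id,
                            population = pedigree$population)
  gm <- geno_matrix(calls, samples, map)

  tracts <- purrr::map_dfr(seq_len(n_ind), function(i) {
    ibd <- L1[i, ] == L2[i, ]
    if (!any(ibd)) return(NULL)
    purrr::map_dfr(chrom_idx, function(ci) {
      # a tract ends when IBD stops or the shared label changes, so encode
      # non-IBD SNPs with unique negative labels and take maximal rle blocks
      lab <- ifelse(ibd[ci], L1[i, ci], -seq_along(ci))
      rr <- rle(lab)
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths + 1L
      keep <- rr$values > 0
      if (!any(keep)) return(NULL)
      tibble::tibble(sample_id = pedigree$id[i],
                     chrom = map$chrom[ci[1]],
                     start_bp = map$pos_bp[ci[starts[keep]]],
                     end_bp = map$pos_bp[ci[ends[keep]]])
    })
  })
  if (nrow(tracts)) {
    tracts$length_bp <- tracts$end_bp - tracts$start_bp + 1
  } else {
    tracts <- tibble::tibble(sample_id = character(), chrom = integer(),
                             start_bp = numeric(), end_bp = numeric(),
                             length_bp = numeric())
  }

  structure(list(
    gm = gm,
    truth = list(tracts = tracts, pedigree_f = pedigree_f(pedigree),
                 ancestral = tibble::tibble(snp_id = map$snp_id,
                                            ancestral = founders$ancestral)),
    pedigree = pedigree),
    class = "sim_drop")
}

#' Apply genotyping noise and attach annotations and an outgroup
#'
#' Masks calls to missing and flips calls to one of the other two genotypes
#' at the configured per-call rates; assigns consequence classes
#' (SYNONYMOUS/MISSENSE/LOF, remainder OTHER) and SIFT scores for missense
#' SNPs; and samples an outgroup panel whose per-SNP ancestral-allele
#' frequency is Beta(9, 1)-distributed (mostly near fixation for the true
#' ancestral allele, with drift noise) realized as binomially resampled
#' haplotypes. Under `deleterious_placement = "enriched_in_recent_haplotypes"`
#' the damaging labels (LOF and SIFT-deleterious missense) are drawn with
#' probability increasing in the number of derived homozygotes the SNP shows
#' inside long (>= 4 Mb) true IBD tracts, planting the enrichment of damaging
#' homozygotes in long ROH.
#'
#' @param drop A [gene_drop()] result (or any list with `gm` and `truth`).
#' @param cfg The [sim_config()].
#' @return A list of class `sim_cohort`: `gm` (noisy), `annotations`
#'   (`snp_id`, `consequence`, `sift_score`), `outgroup` (a [geno_matrix()]
#'   on the same map), `truth` (with `annotations` and true
#'   `outgroup_freq_anc` added), `pedigree`, `build`.
#' @export
inject_noise_and_annotations <- function(drop, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gm <- drop$gm
  truth <- drop$truth
  map <- gm$map
  n_snp <- nrow(map)

  withr::with_seed(cfg$seed + 2L, {
    calls <- gm$calls
    n_cell <- length(calls)
    if (cfg$genotype_error_rate > 0) {
      err <- which(stats::runif(n_cell) < cfg$genotype_error_rate &
                     !is.na(calls))
      if (length(err)) {
        shift <- sample(1:2, length(err), replace = TRUE)
        calls[err] <- (calls[err] + shift) %% 3L
      }
    }
    if (cfg$genotype_missing_rate > 0) {
      calls[stats::runif(n_cell) < cfg$genotype_missing_rate] <- NA_integer_
    }

    spec <- cfg$annotation_spec
    n_lof <- round(spec$p_lof * n_snp)
    n_mis <- round(spec$p_missense * n_snp)
    n_syn <- round(spec$p_synonymous * n_snp)
    n_del_mis <- round(spec$deleterious_fraction * n_mis)

    weights <- rep(1, n_snp)
    if (cfg$deleterious_placement == "enriched_in_recent_haplotypes" &&
        nrow(truth$tracts)) {
      long <- truth$tracts[truth$tracts$length_bp >= 4e6, ]
      score <- numeric(n_snp)
      anc_b <- truth$ancestral$ancestral == "B"
      derived_hom <- ifelse(rep(anc_b, each = nrow(gm$samples)),
                            drop$gm$calls == 0L, drop$gm$calls == 2L)
      dim(derived_hom) <- dim(drop$gm$calls)
      sample_rows <- stats::setNames(seq_len(nrow(gm$samples)),
                                     gm$samples$sample_id)
      for (t in seq_len(nrow(long))) {
        si <- sample_rows[[long$sample_id[t]]]
        vi <- which(map$chrom == long$chrom[t] &
                      map$pos_bp >= long$start_bp[t] &
                      map$pos_bp <= long$end_bp[t])
        score[vi] <- score[vi] + derived_hom[si, vi]
      }
      # concentration, not count: the share of a SNP's derived homozygotes
      # that sit inside long tracts, so high-frequency SNPs are not favored
      total_dh <- colSums(derived_hom, na.rm = TRUE)
      conc <- ifelse(total_dh > 0, score / total_dh, 0)
      if (max(conc) > 0) weights <- 1 + 19 * conc / max(conc)
    }

    damaging_idx <- sample(n_snp, n_lof + n_del_mis, prob = weights)
    lof_idx <- damaging_idx[seq_len(n_lof)]
    del_mis_idx <- setdiff(damaging_idx, lof_idx)
    rest <- setdiff(seq_len(n_snp), damaging_idx)
    tol_mis_idx <- sample(rest, n_mis - n_del_mis)
    rest <- setdiff(rest, tol_mis_idx)
    syn_idx <- sample(rest, n_syn)

    consequence <- rep("OTHER", n_snp)
    consequence[lof_idx] <- "LOF"
    consequence[c(del_mis_idx, tol_mis_idx)] <- "MISSENSE"
    consequence[syn_idx] <- "SYNONYMOUS"
    sift <- rep(NA_real_, n_snp)
    sift[del_mis_idx] <- stats::runif(length(del_mis_idx), 0, 0.05)
    sift[tol_mis_idx] <- stats::runif(length(tol_mis_idx), 0.05 + 1e-9, 1)

    f_anc <- stats::rbeta(n_snp, 9, 1)
    anc_b <- truth$ancestral$ancestral == "B"
    og_freq_b <- ifelse(anc_b, f_anc, 1 - f_anc)
    n_og_hap <- 2L * cfg$outgroup_n
    og_haps <- matrix(stats::rbinom(n_og_hap * n_snp, 1L,
                                    rep(og_freq_b, each = n_og_hap)),
                      nrow = n_og_hap)
    og_calls <- og_haps[seq(1, n_og_hap, 2), , drop = FALSE] +
      og_haps[seq(2, n_og_hap, 2), , drop = FALSE]
  })

  annotations <- tibble::tibble(snp_id = map$snp_id, consequence = consequence,
                                sift_score = sift)
  outgroup <- geno_matrix(
    og_calls,
    tibble::tibble(sample_id = sprintf("out%d", seq_len(cfg$outgroup_n)),
                   population = "outgroup"),
    map)
  truth$annotations <- annotations
  truth$outgroup_freq_anc <- f_anc
  truth$balanced_regions <- cfg$balanced_regions

  structure(list(
    gm = geno_matrix(calls, gm$samples, map),
    annotations = annotations, outgroup = outgroup, truth = truth,
    pedigree = drop$pedigree,
    build = genome_build(stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chrom),
                                         seq_len(cfg$n_chrom)))),
    class = "sim_cohort")
}

#' Simulate a complete cohort in one call
#'
#' Chains [simulate_founders()], [gene_drop()] and
#' [inject_noise_and_annotations()]. With the default pedigree every pool
#' founder becomes one unrelated individual.
#'
#' @param cfg A [sim_config()].
#' @param pedigree Optional pedigree tibble; default [ped_founders()] of
#'   `cfg$founder_count` individuals.
#' @param focal_only Keep only `focal` pedigree individuals in the output
#'   genotype matrix and truth tracts (default TRUE).
#' @return A `sim_cohort` list (see [inject_noise_and_annotations()]).
#' @export
sim_cohort <- function(cfg, pedigree = NULL, focal_only = TRUE) {
  if (is.null(pedigree)) pedigree <- ped_founders(cfg$founder_count)
  founders <- simulate_founders(cfg)
  drop <- gene_drop(founders, pedigree, cfg)
  out <- inject_noise_and_annotations(drop, cfg)
  if (focal_only && !all(pedigree$focal)) {
    keep <- pedigree$id[pedigree$focal]
    out$gm <- subset_geno(out$gm, samples = keep)
    out$truth$tracts <- out$truth$tracts[
      out$truth$tracts$sample_id %in% keep, ]
    out$truth$pedigree_f <- out$truth$pedigree_f[
      out$truth$pedigree_f$sample_id %in% keep, ]
  }
  out
}
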