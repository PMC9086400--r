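test_that("polarization follows the majority rule with an unpolarized tie", {
  gm <- make_gm(matrix(0L, 2, 3))
  freqs <- tibble::tibble(snp_id = c("m1", "m2", "m3"),
                          freq_b = c(0.9, 0.5, 0.2))
  anc <- polarize_ancestral(gm, freqs)
  expect_equal(anc$ancestral, c("B", "UNPOLARIZED", "A"))

  # from outgroup genotypes: 3 of 4 chromosomes carry B at m1
  og <- make_gm(rbind(c(2L, 1L, 0L), c(1L, 1L, 0L)), population = "out")
  anc2 <- polarize_ancestral(gm, og)
  expect_equal(anc2$ancestral, c("B", "UNPOLARIZED", "A"))

  bad <- tibble::tibble(snp_id = "zz", freq_b = 0.9)
  expect_error(polarize_ancestral(gm, bad), "overlap")
})

test_that("simulated outgroup polarization is accurate where the outgroup is decided", {
  sim <- sim_cohort(sim_config(founder_count = 40, seed = 55))
  anc <- polarize_ancestral(sim$gm, sim$outgroup)
  truth <- sim$truth$ancestral
  decided <- sim$truth$outgroup_freq_anc >= 0.7
  m <- anc$ancestral[decided]
  t <- truth$ancestral[decided]
  ok <- m != "UNPOLARIZED"
  expect_gte(mean(m[ok] == t[ok]), 0.95)
})

test_that("deleterious/tolerated/damaging flags follow the SIFT rule and set algebra", {
  ann <- tibble::tibble(
    snp_id = c("a", "b", "c", "d", "e"),
    consequence = c("MISSENSE", "MISSENSE", "LOF", "SYNONYMOUS", "OTHER"),
    sift_score = c(0.05, 0.051, NA, NA, NA))
  fl <- classify_deleterious(ann)
  expect_true(fl$deleterious[fl$snp_id == "a"])   # inclusive threshold
  expect_true(fl$tolerated[fl$snp_id == "b"])
  expect_true(fl$damaging[fl$snp_id == "c"])      # LOF damaging...
  expect_false(fl$deleterious[fl$snp_id == "c"])  # ...but not SIFT-deleterious
  expect_false(any(fl$damaging[fl$snp_id %in% c("b", "d", "e")]))

  withr::local_seed(77)
  rnd <- tibble::tibble(
    snp_id = sprintf("s%d", 1:200),
    consequence = sample(c("MISSENSE", "LOF", "SYNONYMOUS", "OTHER"), 200,
                         replace = TRUE),
    sift_score = runif(200))
  rnd$sift_score[rnd$consequence != "MISSENSE"] <- NA
  fl2 <- classify_deleterious(rnd, 0.1)
  del <- rnd$snp_id[rnd$consequence == "MISSENSE" & rnd$sift_score <= 0.1]
  lof <- rnd$snp_id[rnd$consequence == "LOF"]
  expect_setequal(fl2$snp_id[fl2$deleterious], del)
  expect_setequal(fl2$snp_id[fl2$damaging], union(del, lof))
  expect_setequal(fl2$snp_id[fl2$tolerated],
                  setdiff(rnd$snp_id[rnd$consequence == "MISSENSE"], del))

  # multi-consequence SNPs collapse by severity (LOF wins)
  dup <- tibble::tibble(snp_id = c("x", "x"),
                        consequence = c("SYNONYMOUS", "LOF"),
                        sift_score = c(NA, NA))
  expect_equal(classify_deleterious(dup)$consequence, "LOF")
})

test_that("load ratios reproduce direct counts, dosage weighting included", {
  # 1 sample; sites: 2 del het, 1 del hom-derived, 4 syn het, 3 syn hom-derived
  # ancestral A everywhere, so derived hom = code 2
  calls <- matrix(c(1L, 1L, 2L, rep(1L, 4), rep(2L, 3), 0L), 1)
  gm <- geno_matrix(calls,
                    data.frame(sample_id = "s1", population = "p"),
                    data.frame(snp_id = sprintf("v%d", 1:11), chrom = 1L,
                               pos_bp = (1:11) * 1e5))
  ann <- tibble::tibble(
    snp_id = sprintf("v%d", 1:11),
    consequence = c(rep("MISSENSE", 3), rep("SYNONYMOUS", 8)),
    sift_score = c(0.01, 0.02, 0.03, rep(NA, 8)))
  anc <- tibble::tibble(snp_id = sprintf("v%d", 1:11),
                        outgroup_freq_b = 0.1, ancestral = "A")
  ld <- genetic_load(gm, ann, anc)
  ps <- ld$per_sample
  expect_equal(ps$n_del_het, 2L)
  expect_equal(ps$n_del_hom, 1L)
  expect_equal(ps$n_syn_het, 4L)
  expect_equal(ps$n_syn_hom, 3L)
  expect_equal(ps$load_total, (2 + 2 * 1) / (4 + 2 * 3))  # 0.4
  expect_equal(ps$load_het, 0.5)
  expect_equal(ps$load_hom, 1 / 3)

  # unpolarized sites are excluded from every count
  anc$ancestral[1] <- "UNPOLARIZED"
  ld2 <- genetic_load(gm, ann, anc)
  expect_equal(ld2$per_sample$n_del_het, 1L)

  # zero deleterious sites -> all loads 0
  ann0 <- ann
  ann0$consequence[1:3] <- "SYNONYMOUS"
  ann0$sift_score[1:3] <- NA
  ld0 <- genetic_load(gm, ann0, tibble::tibble(
    snp_id = sprintf("v%d", 1:11), outgroup_freq_b = 0.1, ancestral = "A"))
  expect_equal(ld0$per_sample$load_total, 0)

  # zero synonymous denominator flags undefined
  ann_na <- ann
  ann_na$consequence[4:11] <- "OTHER"
  ldna <- genetic_load(gm, ann_na, anc)
  expect_true(ldna$per_sample$undefined)
})

test_that("derived-allele orientation follows the ancestral call", {
  # ancestral B: derived hom = code 0
  calls <- matrix(c(0L, 2L), 1)
  gm <- geno_matrix(calls,
                    data.frame(sample_id = "s1", population = "p"),
                    data.frame(snp_id = c("d1", "y1"), chrom = 1L,
                               pos_bp = c(1e5, 2e5)))
  ann <- tibble::tibble(snp_id = c("d1", "y1"),
                        consequence = c("MISSENSE", "SYNONYMOUS"),
                        sift_score = c(0.01, NA))
  anc <- tibble::tibble(snp_id = c("d1", "y1"), outgroup_freq_b = 0.9,
                        ancestral = "B")
  ld <- genetic_load(gm, ann, anc)
  expect_equal(ld$per_sample$n_del_hom, 1L)  # code 0 is derived hom here
  expect_equal(ld$per_sample$n_syn_hom, 0L)  # code 2 is ancestral hom here
})

test_that("damaging homozygotes are partitioned over ROH classes exactly", {
  # one sample with a 5-Mb (long) and a 1-Mb (medium) run
  runs <- tibble::tibble(
    sample_id = "s1", population = "p", chrom = 1L,
    start_bp = c(10e6, 30e6), end_bp = c(15e6 - 1, 31e6 - 1),
    n_snps = 100L, n_opposite = 0L, n_missing = 0L,
    length_bp = c(5e6, 1e6), run_type = "ROH")
  # damaging hom on the long run's start (inside), inside the long run,
  # inside the medium run, and outside any run
  pos <- c(10e6, 12e6, 30.5e6, 45e6)
  calls <- matrix(2L, 1, 4)
  gm <- geno_matrix(calls,
                    data.frame(sample_id = "s1", population = "p"),
                    data.frame(snp_id = sprintf("d%d", 1:4), chrom = 1L,
                               pos_bp = pos))
  ann <- tibble::tibble(snp_id = sprintf("d%d", 1:4), consequence = "LOF",
                        sift_score = NA_real_)
  anc <- tibble::tibble(snp_id = sprintf("d%d", 1:4), outgroup_freq_b = 0.1,
                        ancestral = "A")
  res <- damaging_in_roh(runs, gm, ann, anc, genome_build(c(`1` = 50e6)))
  ps <- res$per_sample
  get <- function(cl, col) ps[[col]][ps$roh_class == cl]
  expect_equal(get("B", "n_damaging"), 2L)  # endpoint 10 Mb counts as inside
  expect_equal(get("A", "n_damaging"), 1L)
  expect_equal(get("N", "n_damaging"), 1L)
  expect_equal(get("R", "n_damaging"), 3L)
  expect_equal(get("A", "G"), 1e6 / 50e6)
  expect_equal(get("B", "G"), 5e6 / 50e6)
  expect_equal(get("R", "G") + get("N", "G"), 1, tolerance = 1e-9)
  expect_equal(get("B", "damaging_fraction"), 0.5)

  # a sample with no ROH puts everything in N with G_R = 0
  res0 <- damaging_in_roh(runs[0, ], gm, ann, anc,
                          genome_build(c(`1` = 50e6)))
  expect_equal(res0$per_sample$G[res0$per_sample$roh_class == "R"], 0)
  expect_equal(res0$per_sample$n_damaging[res0$per_sample$roh_class == "N"],
               4L)

  # overlapping runs are an internal error
  bad <- runs
  bad$start_bp[2] <- 14e6
  bad$end_bp[2] <- 16e6
  expect_error(damaging_in_roh(bad, gm, ann, anc,
                               genome_build(c(`1` = 50e6))), "overlap")
})

test_that("class counts conserve totals and G identities hold on a cohort", {
  sim <- small_sim(seed = 60)
  roh <- detect_runs(sim$gm, run_params("ROH", min_snps = 10,
                                        min_length_bp = 5e5))
  anc <- polarize_ancestral(sim$gm, sim$outgroup)
  res <- damaging_in_roh(roh, sim$gm, sim$annotations, anc, sim$build)
  wide <- tidyr::pivot_wider(res$per_sample[, c("sample_id", "roh_class",
                                                "n_damaging", "G")],
                             names_from = "roh_class",
                             values_from = c("n_damaging", "G"))
  expect_equal(wide$n_damaging_A + wide$n_damaging_B, wide$n_damaging_R)
  # genome-wide damaging homozygote count from raw calls
  ann <- classify_deleterious(sim$annotations)
  tab <- dplyr::inner_join(ann, anc, by = "snp_id")
  dmg <- tab$snp_id[tab$damaging & tab$ancestral != "UNPOLARIZED"]
  for (s in seq_len(nrow(sim$gm$samples))) {
    g <- sim$gm$calls[s, dmg]
    anc_s <- tab$ancestral[match(dmg, tab$snp_id)]
    n_tot <- sum(!is.na(g) & g == ifelse(anc_s == "B", 0L, 2L))
    expect_equal(wide$n_damaging_A[s] + wide$n_damaging_B[s] +
                   wide$n_damaging_N[s], n_tot)
  }
  expect_equal(wide$G_A + wide$G_B, wide$G_R, tolerance = 1e-9)
  expect_equal(wide$G_R + wide$G_N, rep(1, nrow(wide)), tolerance = 1e-9)
})
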