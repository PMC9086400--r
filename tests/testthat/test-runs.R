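test_that("minimal ROH emission rules: conformity, SNP count, length", {
  # an all-heterozygous sample has no homozygous stretch
  gm <- make_gm(matrix(1L, 1, 30))
  expect_equal(nrow(detect_runs(gm, run_params("ROH"))), 0)

  # 16 consecutive homozygous calls with one interior heterozygote ->
  # exactly one ROH with n_opposite = 1 (20 SNPs at 100 kb spacing)
  g <- rep(1L, 20)
  g[3:18] <- 0L
  g[10] <- 1L
  gm <- make_gm(matrix(g, 1), pos_bp = seq_len(20) * 1e5)
  roh <- detect_runs(gm, run_params("ROH"))
  expect_equal(nrow(roh), 1)
  expect_equal(roh$n_opposite, 1L)
  expect_equal(roh$start_bp, 3e5)
  expect_equal(roh$end_bp, 18e5)
  expect_equal(roh$length_bp, 18e5 - 3e5 + 1)

  # 14 consecutive homozygous SNPs spanning 1.4 Mb fail the 15-SNP minimum
  g <- rep(1L, 16)
  g[2:15] <- 2L
  gm <- make_gm(matrix(g, 1), pos_bp = seq_len(16) * 1e5)
  expect_equal(nrow(detect_runs(gm, run_params("ROH"))), 0)
  # and pass once a 15th homozygote joins
  g[16] <- 2L
  gm <- make_gm(matrix(g, 1), pos_bp = seq_len(16) * 1e5)
  expect_equal(nrow(detect_runs(gm, run_params("ROH"))), 1)
})

test_that("runs are trimmed to conforming endpoints; allowances are interior", {
  # leading/trailing heterozygotes and missing calls never extend a run
  g <- c(1L, NA, rep(0L, 16), NA, 1L)
  gm <- make_gm(matrix(g, 1), pos_bp = seq_len(20) * 1e5)
  roh <- detect_runs(gm, run_params("ROH"))
  expect_equal(nrow(roh), 1)
  expect_equal(roh$start_bp, 3e5)
  expect_equal(roh$end_bp, 18e5)
  expect_equal(roh$n_opposite, 0L)
  expect_equal(roh$n_missing, 0L)
})

test_that("a gap larger than max_gap_bp splits a run", {
  pos <- c(seq_len(16) * 1e5, 16e5 + 1.2e6 + seq_len(16) * 1e5)
  gm <- make_gm(matrix(0L, 1, 32), pos_bp = pos)
  roh <- detect_runs(gm, run_params("ROH"))
  expect_equal(nrow(roh), 2)
  # with a permissive gap the two halves merge
  roh2 <- detect_runs(gm, run_params("ROH", max_gap_bp = 2e6))
  expect_equal(nrow(roh2), 1)
})

test_that("ROHet detection mirrors ROH with inverted conformity", {
  g <- rep(0L, 20)
  g[3:18] <- 1L
  g[8] <- 2L  # one homozygote allowed (max 3)
  gm <- make_gm(matrix(g, 1), pos_bp = seq_len(20) * 1e5)
  het <- detect_runs(gm, run_params("ROHET"))
  expect_equal(nrow(het), 1)
  expect_equal(het$n_opposite, 1L)
  expect_equal(het$run_type, "ROHET")
})

test_that("detect_runs equals the exhaustive oracle on random matrices", {
  withr::local_seed(404)
  for (rep in 1:40) {
    gm <- random_gm(sample(2:8, 1), sample(40:120, 1),
                    missing_rate = runif(1, 0, 0.15))
    params <- run_params(sample(c("ROH", "ROHET"), 1),
                         min_snps = sample(3:15, 1),
                         min_length_bp = sample(c(0, 2e5, 5e5), 1),
                         max_opposite = sample(0:3, 1),
                         max_missing = sample(0:2, 1),
                         max_gap_bp = sample(c(3e5, 1e6), 1))
    got <- detect_runs(gm, params)
    ref <- oracle_detect_runs(gm, params)
    got_key <- sort(paste(got$sample_id, got$chrom, got$start_bp, got$end_bp))
    ref_key <- sort(paste(ref$sample_id, ref$chrom, ref$start_bp, ref$end_bp))
    expect_identical(got_key, ref_key)
  }
})

test_that("raising min_snps or min_length never increases the run count", {
  withr::local_seed(505)
  gm <- random_gm(10, 150, missing_rate = 0.05)
  counts_snps <- vapply(c(3, 5, 10, 20), function(ms) {
    nrow(detect_runs(gm, run_params("ROH", min_snps = ms, min_length_bp = 0)))
  }, numeric(1))
  expect_true(all(diff(counts_snps) <= 0))
  counts_len <- vapply(c(0, 2e5, 5e5, 1e6), function(ml) {
    nrow(detect_runs(gm, run_params("ROH", min_snps = 3, min_length_bp = ml)))
  }, numeric(1))
  expect_true(all(diff(counts_len) <= 0))
})

test_that("ROH and ROHet never share a conforming SNP at max_opposite = 0", {
  sim <- small_sim(seed = 77)
  p_roh <- run_params("ROH", max_opposite = 0)
  p_het <- run_params("ROHET", max_opposite = 0, min_snps = 5,
                      min_length_bp = 1e5)
  roh <- detect_runs(sim$gm, p_roh)
  het <- detect_runs(sim$gm, p_het)
  for (sid in intersect(roh$sample_id, het$sample_id)) {
    r1 <- roh[roh$sample_id == sid, ]
    r2 <- het[het$sample_id == sid, ]
    for (j in seq_len(nrow(sim$gm$map))) {
      cc <- sim$gm$map$chrom[j]; pp <- sim$gm$map$pos_bp[j]
      in1 <- any(r1$chrom == cc & r1$start_bp <= pp & r1$end_bp >= pp)
      in2 <- any(r2$chrom == cc & r2$start_bp <= pp & r2$end_bp >= pp)
      g <- sim$gm$calls[sid, j]
      if (!is.na(g) && in1 && in2) {
        # a SNP inside both runs must be non-conforming for one of them,
        # which cannot happen for a called genotype
        fail(sprintf("SNP %d shared by ROH and ROHet", j))
      }
    }
  }
  succeed()
})

test_that("length classes use half-open bins with the documented boundaries", {
  expect_equal(as.character(run_length_class(2e6, "ROH")), "2-4Mb")
  expect_equal(as.character(run_length_class(16e6, "ROH")), ">16Mb")
  expect_equal(as.character(run_length_class(1.5e6, "ROHET")), "1.5-2Mb")

  empty <- classify_runs(tibble::tibble(length_bp = numeric(),
                                        run_type = character()), "ROH")
  expect_equal(empty$n_runs, rep(0L, 5))

  withr::local_seed(606)
  lens <- runif(100, 0.5e6, 30e6)
  runs <- tibble::tibble(length_bp = lens, run_type = "ROH")
  cs <- classify_runs(runs, "ROH")
  # brute-force comparison chain
  ref <- vapply(lens, function(l) {
    if (l < 2e6) "0.5-2Mb" else if (l < 4e6) "2-4Mb" else if (l < 8e6) "4-8Mb"
    else if (l < 16e6) "8-16Mb" else ">16Mb"
  }, character(1))
  expect_equal(cs$n_runs, as.integer(table(factor(ref, cs$class_label))))
  expect_equal(sum(cs$n_runs), 100L)
})

test_that("summaries recount runs, coverage and flag degenerate CVs", {
  # one sample, one 1-Mb run on a 100-Mb chromosome -> 1% coverage
  runs <- tibble::tibble(sample_id = "s1", population = "p", chrom = 1L,
                         start_bp = 5e6, end_bp = 5e6 + 1e6 - 1,
                         n_snps = 20L, n_opposite = 0L, n_missing = 0L,
                         length_bp = 1e6, run_type = "ROH")
  gm <- make_gm(matrix(0L, 1, 20), population = "p")
  sm <- summarize_runs(runs, gm, genome_build(c(`1` = 1e8)))
  expect_equal(sm$per_chromosome$coverage_pct, 1.0)
  expect_true(sm$per_population$cv_undefined)
  expect_true(sm$count_length_cor$undefined)

  # no runs at all
  sm0 <- summarize_runs(runs[0, ], gm, genome_build(c(`1` = 1e8)))
  expect_equal(sm0$per_sample$total_length_bp, 0)
  expect_true(sm0$count_length_cor$undefined)

  # simulated cohort: per-sample totals equal brute-force summation
  sim <- small_sim(seed = 88)
  roh <- detect_runs(sim$gm, run_params("ROH", min_snps = 10,
                                        min_length_bp = 2e5))
  sm2 <- summarize_runs(roh, sim$gm, sim$build)
  for (sid in sim$gm$samples$sample_id) {
    expect_equal(
      sm2$per_sample$total_length_bp[sm2$per_sample$sample_id == sid],
      sum(roh$length_bp[roh$sample_id == sid]))
  }
  gl <- glance(sm2)
  expect_equal(gl$total_runs, nrow(roh))
  expect_equal(nrow(tidy(sm2)), nrow(sim$gm$samples))
})

test_that("true autozygous tracts are recovered by emitted ROH", {
  cfg <- sim_config(founder_count = 60, seed = 99)
  sim <- sim_cohort(cfg, ped_full_sib_families(30))
  roh <- detect_runs(sim$gm, run_params("ROH"))
  tracts <- sim$truth$tracts[sim$truth$tracts$length_bp >= 1e6, ]
  expect_gt(nrow(tracts), 10)
  for (i in seq_len(nrow(tracts))) {
    tr <- tracts[i, ]
    rr <- roh[roh$sample_id == tr$sample_id & roh$chrom == tr$chrom, ]
    cov <- sum(pmax(0, pmin(rr$end_bp, tr$end_bp) -
                      pmax(rr$start_bp, tr$start_bp) + 1))
    expect_gte(cov / tr$length_bp, 0.9)
  }
})
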