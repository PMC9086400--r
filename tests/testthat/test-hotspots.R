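test_that("incidence counts individuals covered at each SNP", {
  gm <- make_gm(matrix(0L, 4, 10), pos_bp = (1:10) * 1e5)
  empty_runs <- tibble::tibble(sample_id = character(), population = character(),
                               chrom = integer(), start_bp = numeric(),
                               end_bp = numeric(), length_bp = numeric(),
                               run_type = character())
  tr0 <- run_incidence(empty_runs, gm)
  expect_true(all(tr0$percent == 0))

  runs <- tibble::tibble(sample_id = "s1", population = "pop1", chrom = 1L,
                         start_bp = 2e5, end_bp = 5e5, length_bp = 3e5 + 1,
                         run_type = "ROH")
  tr <- run_incidence(runs, gm)
  expect_equal(tr$percent, c(0, 25, 25, 25, 25, 0, 0, 0, 0, 0))
  expect_error(run_incidence(runs, gm, population = "nope"), "population")
})

test_that("incidence equals a brute-force point-in-interval recount", {
  withr::local_seed(909)
  gm <- random_gm(8, 60, missing_rate = 0)
  runs <- purrr::map_dfr(1:20, function(i) {
    cc <- sample(1:2, 1)
    pos <- sort(sample(gm$map$pos_bp[gm$map$chrom == cc], 2))
    tibble::tibble(sample_id = sample(gm$samples$sample_id, 1),
                   population = "pop1", chrom = cc,
                   start_bp = pos[1], end_bp = pos[2],
                   length_bp = pos[2] - pos[1] + 1, run_type = "ROH")
  })
  # de-overlap per sample by keeping the first run per (sample, chrom)
  runs <- runs[!duplicated(runs[, c("sample_id", "chrom")]), ]
  tr <- run_incidence(runs, gm)
  expect_equal(tr$percent, oracle_incidence(runs, gm, "pop1"))
})

test_that("hotspot threshold is the stated order statistic, ties included", {
  withr::local_seed(910)
  n <- 1000
  percent <- c(runif(n - 10, 0, 20), runif(10, 60, 90))[sample(n)]
  track <- tibble::tibble(population = "p", snp_id = sprintf("m%d", 1:n),
                          chrom = 1L, pos_bp = (1:n) * 1e5,
                          percent = percent, n_covered = 0L)
  hs <- call_hotspots(track, top_fraction = 0.005)
  thr_ref <- sort(percent)[ceiling(0.995 * n)]
  expect_equal(unique(hs$threshold_used), thr_ref)
  sel_ref <- track$snp_id[track$percent >= thr_ref]
  expect_setequal(unlist(hs$snp_ids), sel_ref)
  # union of region SNPs = selected set, no duplication
  expect_equal(sum(hs$n_snps), length(sel_ref))

  # raising the fraction never shrinks the selected set
  hs2 <- call_hotspots(track, top_fraction = 0.02)
  expect_true(all(unlist(hs$snp_ids) %in% unlist(hs2$snp_ids)))
})

test_that("an implanted high-incidence block becomes exactly one region", {
  withr::local_seed(911)
  n <- 2000
  percent <- runif(n, 0, 9)          # background incidence < 10%
  percent[100:119] <- 90             # 20-SNP IBD block shared by 90%
  track <- tibble::tibble(population = "p", snp_id = sprintf("m%d", 1:n),
                          chrom = rep(1:2, each = n / 2),
                          pos_bp = rep((1:(n / 2)) * 5e4, 2),
                          percent = percent, n_covered = 0L)
  hs <- call_hotspots(track, top_fraction = 0.005)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$start_bp, 100 * 5e4)
  expect_equal(hs$end_bp, 119 * 5e4)
  expect_equal(hs$n_snps, 20L)
  expect_equal(hs$max_percent, 90)
})

test_that("a constant track warns and selects everything", {
  track <- tibble::tibble(population = "p", snp_id = sprintf("m%d", 1:50),
                          chrom = 1L, pos_bp = (1:50) * 1e5,
                          percent = 5, n_covered = 1L)
  expect_warning(hs <- call_hotspots(track, 0.01), "constant")
  expect_equal(sum(hs$n_snps), 50L)
})

test_that("regions merge only across SNPs adjacent in map order", {
  track <- tibble::tibble(population = "p", snp_id = sprintf("m%d", 1:12),
                          chrom = rep(1:2, each = 6),
                          pos_bp = rep((1:6) * 1e5, 2),
                          percent = c(0, 50, 50, 0, 50, 50,
                                      50, 50, 0, 0, 0, 0), n_covered = 0L)
  hs <- call_hotspots(track, top_fraction = 0.4)
  # blocks: chr1 2-3, chr1 5-6, chr2 1-2 (no merging across the gap or the
  # chromosome boundary)
  expect_equal(nrow(hs), 3)
  expect_equal(hs$chrom, c(1L, 1L, 2L))
  expect_equal(hs$n_snps, c(2L, 2L, 2L))
})

test_that("gene windows are +/-50 kb, clipped, and intersected correctly", {
  genes <- tibble::tibble(chrom = c(1L, 1L, 1L, 2L, 2L),
                          start_bp = c(900000, 1200000, 5000000, 30000, 800000),
                          end_bp = c(960000, 1300000, 5100000, 50000, 900000),
                          name = c("g1", "g2", "g3", "g4", "g5"))
  snps <- tibble::tibble(snp_id = c("a", "b", "c"),
                         chrom = c(1L, 1L, 2L),
                         pos_bp = c(1000000, 3000000, 10000))
  gw <- gene_windows(snps, genes)
  # manual overlap list: a->g1 (window 950k-1050k), c->g4 (window 1-60k);
  # b's window 2.95-3.05 Mb touches nothing; g2 starts 150 kb past a's SNP
  expect_setequal(paste(gw$snp_id, gw$gene),
                  c("a g1", "c g4"))
  expect_equal(gw$win_start_bp[gw$snp_id == "a"], 950000)
  expect_equal(gw$win_end_bp[gw$snp_id == "a"], 1050000)
  expect_equal(gw$win_start_bp[gw$snp_id == "c"], 1)  # clipped at 1

  # clipping at the chromosome end
  build <- genome_build(c(`1` = 3.02e6, `2` = 1e6))
  gw2 <- gene_windows(snps, genes, build = build)
  expect_equal(gw2$win_end_bp[gw2$snp_id == "c"], 60000)
  b_win <- gene_windows(snps[2, ], genes, build = build)
  expect_equal(nrow(b_win), 0)

  expect_error(gene_windows(dplyr::mutate(snps, chrom = 9L), genes),
               "chromosome")
})

test_that("gene annotations load from BED and GFF3", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "g.bed")
  writeLines(c("1\t899999\t960000\tg1", "2\t29999\t50000\tg4"), bed)
  gb <- read_gene_annotation(bed)
  expect_equal(gb$start_bp, c(900000, 30000))  # 0-based BED -> 1-based
  expect_equal(gb$name, c("g1", "g4"))

  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t900000\t960000\t.\t+\t.\tID=g1;Name=g1",
               "1\tsrc\texon\t900000\t910000\t.\t+\t.\tID=g1.e1"), gff)
  gg <- read_gene_annotation(gff)
  expect_equal(nrow(gg), 1)
  expect_equal(gg$name, "g1")
})

test_that("shared hotspots are the genomic intersection of region sets", {
  a <- tibble::tibble(population = "p1", chrom = c(1L, 1L, 2L),
                      start_bp = c(1e6, 5e6, 2e6),
                      end_bp = c(2e6, 6e6, 3e6))
  # identical sets intersect to themselves
  same <- shared_hotspots(list(a, a))
  expect_equal(nrow(same), 3)
  expect_equal(same$start_bp, c(1e6, 5e6, 2e6)[order(c(1, 1, 2))])

  b <- tibble::tibble(population = "p2", chrom = c(1L, 2L),
                      start_bp = c(1.5e6, 10e6), end_bp = c(5.5e6, 11e6))
  got <- shared_hotspots(list(a, b))
  ref <- oracle_intersect(a, b)
  expect_equal(nrow(got), nrow(ref))
  expect_setequal(paste(got$chrom, got$start_bp, got$end_bp),
                  paste(ref$chrom, ref$start_bp, ref$end_bp))

  disjoint <- tibble::tibble(population = "p3", chrom = 1L,
                             start_bp = 8e6, end_bp = 9e6)
  expect_equal(nrow(shared_hotspots(list(a, disjoint))), 0)

  # random interval sets against the brute-force intersection
  withr::local_seed(912)
  for (rep in 1:5) {
    mk <- function() {
      s <- sort(sample(1:100, 6)) * 1e5
      tibble::tibble(population = "x", chrom = sample(1:2, 3, TRUE),
                     start_bp = s[c(1, 3, 5)], end_bp = s[c(2, 4, 6)])
    }
    x <- mk(); y <- mk()
    got <- shared_hotspots(list(x, y))
    ref <- oracle_intersect(x, y)
    # brute force may emit abutting duplicates; compare covered positions
    cover <- function(df) {
      if (is.null(df) || nrow(df) == 0) return(character(0))
      unlist(lapply(seq_len(nrow(df)), function(i) {
        paste(df$chrom[i], seq(df$start_bp[i], df$end_bp[i], by = 1e5))
      }))
    }
    expect_setequal(unique(cover(got)), unique(cover(ref)))
  }
})

test_that("shared hotspots can report member SNPs from a map", {
  a <- tibble::tibble(population = "p1", chrom = 1L, start_bp = 1e6,
                      end_bp = 2e6)
  b <- tibble::tibble(population = "p2", chrom = 1L, start_bp = 1.5e6,
                      end_bp = 3e6)
  map <- tibble::tibble(snp_id = sprintf("m%d", 1:30), chrom = 1L,
                        pos_bp = (1:30) * 1e5)
  got <- shared_hotspots(dplyr::bind_rows(a, b), map = map)
  expect_equal(got$start_bp, 1.5e6)
  expect_equal(got$end_bp, 2e6)
  expect_equal(got$snp_ids[[1]], sprintf("m%d", 15:20))
})
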