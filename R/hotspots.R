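#' Per-SNP run incidence within populations
#'
#' For every SNP and population, the percentage of the population's
#' individuals whose runs (of one type) cover the SNP position. The
#' denominator is the full population, individuals without any run included.
#'
#' @param runs A run tibble of a single run type from [detect_runs()].
#' @param gm The [geno_matrix()] the runs came from (supplies population
#'   sizes and the marker map).
#' @param population Optional character vector restricting to some
#'   populations; default all populations in `gm`.
#' @return An incidence track tibble: `population`, `snp_id`, `chrom`,
#'   `pos_bp`, `n_covered`, `percent`, in map order within population.
#' @export
run_incidence <- function(runs, gm, population = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(runs) && length(unique(runs$run_type)) > 1) {
    stop("runs must be of a single type", call. = FALSE)
  }
  pops <- if (is.null(population)) {
    unique(gm$samples$population)
  } else {
    population
  }
  if (!length(pops) || !any(gm$samples$population %in% pops)) {
    stop("empty population", call. = FALSE)
  }
  map <- gm$map
  purrr::map_dfr(pops, function(pp) {
    ids <- gm$samples$sample_id[gm$samples$population == pp]
    if (!length(ids)) stop("empty population: ", pp, call. = FALSE)
    cover <- integer(nrow(map))
    rr <- runs[runs$sample_id %in% ids, ]
    # runs of one individual never overlap, so each run adds at most one
    # count per (individual, SNP)
    for (k in seq_len(nrow(rr))) {
      idx <- which(map$chrom == rr$chrom[k] & map$pos_bp >= rr$start_bp[k] &
                     map$pos_bp <= rr$end_bp[k])
      cover[idx] <- cover[idx] + 1L
    }
    tibble::tibble(population = pp, snp_id = map$snp_id, chrom = map$chrom,
                   pos_bp = map$pos_bp, n_covered = cover,
                   percent = 100 * cover / length(ids))
  })
}

#' Call hotspot regions from an incidence track
#'
#' The threshold is the incidence value at the `ceiling((1 - f) n)`-th
#' ascending order statistic of the per-SNP percent distribution of the
#' population (all panel SNPs, zero-incidence SNPs included), with
#' `f = top_fraction` (0.005 for ROH hotspots, 0.001 for ROHet hotspots).
#' SNPs at or above the threshold are selected (ties included) and SNPs
#' adjacent in map order on the same chromosome are merged into maximal
#' regions.
#'
#' @param track An incidence track from [run_incidence()] (may hold several
#'   populations; thresholds are population-specific).
#' @param top_fraction Upper tail fraction defining the threshold.
#' @return A hotspot tibble: `population`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `max_percent`, `threshold_used`, plus a `snp_ids`
#'   list-column of member SNPs. A constant track selects every SNP, with a
#'   warning.
#' @export
call_hotspots <- function(track, top_fraction = 0.005) {
  stopifnot(nrow(track) > 0, top_fraction > 0, top_fraction < 1)
  purrr::map_dfr(unique(track$population), function(pp) {
    tr <- track[track$population == pp, ]
    tr <- tr[order(tr$chrom, tr$pos_bp), ]
    n <- nrow(tr)
    thr <- sort(tr$percent)[ceiling((1 - top_fraction) * n)]
    if (length(unique(tr$percent)) == 1) {
      warning("constant incidence track for population ", pp,
              "; every SNP selected", call. = FALSE)
    }
    sel <- tr$percent >= thr
    if (!any(sel)) return(NULL)
    # merge runs of adjacent selected SNPs per chromosome
    grp <- cumsum(c(TRUE, diff(which(sel)) > 1 |
                      diff(tr$chrom[sel]) != 0))
    sel_idx <- which(sel)
    purrr::map_dfr(split(sel_idx, grp), function(idx) {
      tibble::tibble(population = pp, chrom = tr$chrom[idx[1]],
                     start_bp = tr$pos_bp[idx[1]],
                     end_bp = tr$pos_bp[idx[length(idx)]],
                     n_snps = length(idx),
                     max_percent = max(tr$percent[idx]),
                     threshold_used = thr,
                     snp_ids = list(tr$snp_id[idx]))
    })
  })
}

#' Candidate genes around hotspot SNPs
#'
#' Expands each candidate SNP to a 100-kb window (50 kb upstream and 50 kb
#' downstream), clips the window at position 1 and at the chromosome end,
#' and reports every gene overlapping a window.
#'
#' @param snps Tibble of candidate SNPs: `snp_id`, `chrom`, `pos_bp`.
#' @param genes Gene annotation tibble: `chrom`, `start_bp`, `end_bp`,
#'   `name` (see [read_gene_annotation()] for BED/GFF3 input).
#' @param flank_bp Flank on each side (default 50,000).
#' @param build Optional [genome_build()]; windows are clipped to chromosome
#'   lengths when given.
#' @return A tibble: `snp_id`, `chrom`, `win_start_bp`, `win_end_bp`,
#'   `gene`, `gene_start_bp`, `gene_end_bp`.
#' @export
gene_windows <- function(snps, genes, flank_bp = 50000, build = NULL) {
  snps <- tibble::as_tibble(snps)
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("chrom", "pos_bp") %in% names(snps)),
            all(c("chrom", "start_bp", "end_bp", "name") %in% names(genes)))
  if (!length(intersect(unique(snps$chrom), unique(genes$chrom)))) {
    stop("no shared chromosomes between SNPs and gene annotation ",
         "(mismatched builds?)", call. = FALSE)
  }
  win <- snps %>% dplyr::mutate(
    win_start_bp = pmax(1, .data$pos_bp - flank_bp),
    win_end_bp = .data$pos_bp + flank_bp)
  if (!is.null(build)) {
    len <- stats::setNames(build$length_bp, build$chrom)
    win$win_end_bp <- pmin(win$win_end_bp,
                           len[as.character(win$chrom)])
  }
  purrr::map_dfr(intersect(unique(win$chrom), unique(genes$chrom)),
                 function(cc) {
    w <- win[win$chrom == cc, ]
    g <- genes[genes$chrom == cc, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(w$win_start_bp, w$win_end_bp),
      IRanges::IRanges(g$start_bp, g$end_bp))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (!length(qi)) return(NULL)
    tibble::tibble(
      snp_id = if ("snp_id" %in% names(w)) w$snp_id[qi] else NA_character_,
      chrom = cc,
      win_start_bp = w$win_start_bp[qi], win_end_bp = w$win_end_bp[qi],
      gene = g$name[si],
      gene_start_bp = g$start_bp[si], gene_end_bp = g$end_bp[si])
  })
}

#' Read a gene annotation from BED or GFF3
#'
#' Thin wrapper over `rtracklayer::import()` returning the tibble layout
#' [gene_windows()] expects; BED input (0-based half-open) is converted to
#' 1-based inclusive coordinates by the importer.
#'
#' @param path Path to a `.bed`, `.gff3` or `.gff` file.
#' @param feature For GFF3, the feature type to keep (default "gene").
#' @return A tibble: `chrom`, `start_bp`, `end_bp`, `name`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == feature)) {
    df <- df[df$type == feature, ]
  }
  name <- if ("name" %in% names(df)) {
    df$name
  } else if ("Name" %in% names(df)) {
    df$Name
  } else if ("ID" %in% names(df)) {
    df$ID
  } else {
    paste0("feature", seq_len(nrow(df)))
  }
  tibble::tibble(chrom = as.integer(as.character(df$seqnames)),
                 start_bp = df$start, end_bp = df$end, name = name)
}

#' Hotspot regions shared between populations
#'
#' Genomic intersection of the hotspot regions of two or more populations:
#' a region is reported wherever every population has a hotspot, with the
#' overlapping span and (when a map is given) the member SNPs.
#'
#' @param hotspots A hotspot tibble from [call_hotspots()] holding at least
#'   two populations, or a list of per-population region tibbles.
#' @param map Optional marker map (`snp_id`, `chrom`, `pos_bp`) used to list
#'   the SNPs inside each shared region.
#' @return A tibble: `chrom`, `start_bp`, `end_bp`, and `snp_ids`
#'   list-column when `map` is supplied. Empty when the sets are disjoint.
#' @export
shared_hotspots <- function(hotspots, map = NULL) {
  sets <- if (is.data.frame(hotspots)) {
    split(tibble::as_tibble(hotspots), hotspots$population)
  } else {
    hotspots
  }
  if (length(sets) < 2) {
    stop("need hotspot sets from at least two populations", call. = FALSE)
  }
  as_grl <- function(df) {
    split(IRanges::IRanges(df$start_bp, df$end_bp), df$chrom)
  }
  inter <- purrr::reduce(lapply(sets, as_grl), function(a, b) {
    chroms <- intersect(names(a), names(b))
    out <- lapply(chroms, function(cc) {
      IRanges::intersect(a[[cc]], b[[cc]])
    })
    stats::setNames(out, chroms)
  })
  res <- purrr::map_dfr(names(inter), function(cc) {
    ir <- inter[[cc]]
    if (!length(ir)) return(NULL)
    tibble::tibble(chrom = as.integer(cc),
                   start_bp = as.numeric(IRanges::start(ir)),
                   end_bp = as.numeric(IRanges::end(ir)))
  })
  if (!is.null(map) && nrow(res)) {
    res$snp_ids <- purrr::map2(res$chrom, seq_len(nrow(res)), function(cc, i) {
      map$snp_id[map$chrom == cc & map$pos_bp >= res$start_bp[i] &
                   map$pos_bp <= res$end_bp[i]]
    })
  }
  res
}
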