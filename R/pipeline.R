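#' Configure an end-to-end analysis
#'
#' Collects inputs and parameters for [run_pipeline()]. All thresholds
#' default to the standard chip-data parameterization: call rate and MAF QC,
#' 15-SNP/500-kb runs with 1 heterozygote (ROH) or 3 homozygotes (ROHet) and
#' 2 missing calls allowed, top 0.5% ROH and top 0.1% ROHet hotspot
#' incidence cutoffs, and 250-kb windows for the balancing scan.
#'
#' @param gm A [geno_matrix()], or `NULL` with `ped_path`/`map_path` set.
#' @param ped_path,map_path PED/MAP input files (used when `gm` is NULL).
#' @param annotations Annotation tibble or TSV path (`snp_id`, `consequence`,
#'   `sift_score`); optional, enables the load/enrichment stages.
#' @param outgroup A [geno_matrix()], frequency tibble, or PED/MAP path
#'   prefix; optional, required for the load/enrichment stages.
#' @param genes Gene annotation tibble or BED/GFF3 path; optional.
#' @param build A [genome_build()]; default derived from the map.
#' @param qc A [qc_config()].
#' @param roh,rohet [run_params()] for each run type.
#' @param roh_top_fraction,rohet_top_fraction Hotspot cutoffs.
#' @param window_bp Balancing-scan window width.
#' @param beta [beta_params()].
#' @param out_dir Output directory for TSV/BED exports; `NULL` disables
#'   writing.
#' @param stages Character vector of stages to run, a subset of
#'   `c("qc", "roh", "rohet", "inbreeding", "load", "enrichment",
#'   "hotspots", "balancing")`.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gm = NULL, ped_path = NULL, map_path = NULL,
                            annotations = NULL, outgroup = NULL, genes = NULL,
                            build = NULL, qc = qc_config(),
                            roh = run_params("ROH"),
                            rohet = run_params("ROHET"),
                            roh_top_fraction = 0.005,
                            rohet_top_fraction = 0.001,
                            window_bp = 250000, beta = beta_params(),
                            out_dir = NULL,
                            stages = c("qc", "roh", "rohet", "inbreeding",
                                       "load", "enrichment", "hotspots",
                                       "balancing"),
                            seed = 1L) {
  stopifnot(roh_top_fraction > 0, roh_top_fraction < 1,
            rohet_top_fraction > 0, rohet_top_fraction < 1)
  if (is.null(gm)) {
    if (is.null(ped_path) || is.null(map_path)) {
      stop("supply `gm` or both `ped_path` and `map_path`", call. = FALSE)
    }
    stopifnot(file.exists(ped_path), file.exists(map_path))
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(gm = gm, ped_path = ped_path, map_path = map_path,
                 annotations = annotations, outgroup = outgroup,
                 genes = genes, build = build, qc = qc, roh = roh,
                 rohet = rohet, roh_top_fraction = roh_top_fraction,
                 rohet_top_fraction = rohet_top_fraction,
                 window_bp = window_bp, beta = beta, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (QC, ROH, ROHet, inbreeding,
#' genetic load, ROH enrichment, hotspots, balancing scan), writes each
#' stage's tables as TSV (runs additionally as BED) when `out_dir` is set,
#' and records a manifest with the configuration hash and seed. Any stage
#' failure aborts with the stage name. Output is fully deterministic for a
#' fixed configuration.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  res <- list()
  out <- function(name, df) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
      readr::write_tsv(df, file.path(cfg$out_dir, paste0(name, ".tsv")))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  gm <- cfg$gm %||% stage("input", read_ped_map(cfg$ped_path, cfg$map_path))
  if ("qc" %in% cfg$stages) {
    gm <- stage("qc", apply_qc(gm, cfg$qc))
    res$qc_report <- qc_report(gm)
    out("qc_report", res$qc_report)
  }
  res$gm <- gm
  build <- cfg$build %||% genome_build_from_map(gm$map)

  if ("roh" %in% cfg$stages) {
    res$roh <- stage("roh", detect_runs(gm, cfg$roh))
    res$roh_classes <- classify_runs(res$roh, "ROH")
    res$roh_summary <- summarize_runs(res$roh, gm, build)
    out("roh_runs", res$roh)
    out("roh_classes", res$roh_classes)
    out("roh_per_sample", res$roh_summary$per_sample)
    out("roh_per_population", res$roh_summary$per_population)
    if (!is.null(cfg$out_dir)) {
      runs_to_bed(res$roh, file.path(cfg$out_dir, "roh_runs.bed"))
    }
  }
  if ("rohet" %in% cfg$stages) {
    res$rohet <- stage("rohet", detect_runs(gm, cfg$rohet))
    res$rohet_classes <- classify_runs(res$rohet, "ROHET")
    out("rohet_runs", res$rohet)
    out("rohet_classes", res$rohet_classes)
    if (!is.null(cfg$out_dir)) {
      runs_to_bed(res$rohet, file.path(cfg$out_dir, "rohet_runs.bed"))
    }
  }
  if ("inbreeding" %in% cfg$stages) {
    if (is.null(res$roh)) {
      stop("stage 'inbreeding' needs the 'roh' stage", call. = FALSE)
    }
    res$inbreeding <- stage("inbreeding", {
      fh <- f_hom(gm)
      fr <- f_roh(res$roh, build, samples = gm$samples)
      inbreeding_summary(fh, fr)
    })
    out("inbreeding_per_sample", res$inbreeding$per_sample)
    out("inbreeding_correlations", res$inbreeding$correlations)
  }
  need_ann <- intersect(c("load", "enrichment"), cfg$stages)
  if (length(need_ann)) {
    if (is.null(cfg$annotations) || is.null(cfg$outgroup)) {
      stop("stages ", paste(need_ann, collapse = "/"),
           " need `annotations` and `outgroup`", call. = FALSE)
    }
    ann <- if (is.character(cfg$annotations)) {
      readr::read_tsv(cfg$annotations, show_col_types = FALSE)
    } else {
      cfg$annotations
    }
    anc <- stage("polarize", polarize_ancestral(gm, cfg$outgroup))
    res$ancestral <- anc
    if ("load" %in% cfg$stages) {
      res$load <- stage("load", genetic_load(gm, ann, anc))
      out("load_per_sample", res$load$per_sample)
      out("load_per_population", res$load$per_population)
    }
    if ("enrichment" %in% cfg$stages) {
      if (is.null(res$roh)) {
        stop("stage 'enrichment' needs the 'roh' stage", call. = FALSE)
      }
      res$enrichment <- stage("enrichment",
                              damaging_in_roh(res$roh, gm, ann, anc, build))
      out("enrichment_per_sample", res$enrichment$per_sample)
      out("enrichment_correlations", res$enrichment$correlations)
    }
  }
  if ("hotspots" %in% cfg$stages) {
    if (is.null(res$roh)) {
      stop("stage 'hotspots' needs the 'roh' stage", call. = FALSE)
    }
    res$roh_incidence <- stage("hotspots", run_incidence(res$roh, gm))
    res$roh_hotspots <- call_hotspots(res$roh_incidence,
                                      cfg$roh_top_fraction)
    out("roh_incidence", res$roh_incidence)
    out("roh_hotspots", res$roh_hotspots)
    if (!is.null(res$rohet)) {
      res$rohet_incidence <- run_incidence(res$rohet, gm)
      res$rohet_hotspots <- call_hotspots(res$rohet_incidence,
                                          cfg$rohet_top_fraction)
      out("rohet_incidence", res$rohet_incidence)
      out("rohet_hotspots", res$rohet_hotspots)
    }
    if (!is.null(cfg$genes) && nrow(res$roh_hotspots %||% tibble::tibble())) {
      genes <- if (is.character(cfg$genes)) {
        read_gene_annotation(cfg$genes)
      } else {
        cfg$genes
      }
      hot_snps <- gm$map[gm$map$snp_id %in%
                           unlist(res$roh_hotspots$snp_ids), ]
      res$candidate_genes <- stage("genes",
                                   gene_windows(hot_snps, genes,
                                                build = build))
      out("candidate_genes", res$candidate_genes)
    }
  }
  if ("balancing" %in% cfg$stages) {
    res$balancing <- stage("balancing",
                           balancing_scan(gm, cfg$beta, cfg$window_bp))
    out("balancing_windows", res$balancing)
  }

  if (!is.null(cfg$out_dir)) {
    manifest <- c(
      paste0("config_hash\t", rlang::hash(cfg[setdiff(names(cfg), c("gm", "out_dir"))])),
      paste0("seed\t", cfg$seed),
      paste0("stages\t", paste(cfg$stages, collapse = ",")),
      paste0("n_samples\t", nrow(gm$samples)),
      paste0("n_snps\t", nrow(gm$map)))
    writeLines(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  }
  invisible(res)
}
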