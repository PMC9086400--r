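#' Plot a run-incidence track
#'
#' Per-SNP incidence along each chromosome, faceted by population, with the
#' hotspot threshold drawn when supplied.
#'
#' @param track A track from [run_incidence()].
#' @param hotspots Optional output of [call_hotspots()]; its thresholds are
#'   drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_incidence <- function(track, hotspots = NULL) {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = .data$pos_bp / 1e6,
                                    y = .data$percent)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(population ~ chrom, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position (Mb)", y = "individuals in a run (%)") +
    ggplot2::theme_minimal()
  if (!is.null(hotspots) && nrow(hotspots)) {
    thr <- dplyr::distinct(hotspots[, c("population", "threshold_used")])
    p <- p + ggplot2::geom_hline(data = thr,
                                 ggplot2::aes(yintercept = .data$threshold_used),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot run counts by length class
#'
#' @param class_summary Output of [classify_runs()].
#' @return A ggplot bar chart of counts per length class.
#' @export
plot_run_classes <- function(class_summary) {
  class_summary$class_label <- factor(class_summary$class_label,
                                      levels = class_summary$class_label)
  ggplot2::ggplot(class_summary,
                  ggplot2::aes(x = .data$class_label, y = .data$n_runs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "length class", y = "runs") +
    ggplot2::theme_minimal()
}

#' Plot a window statistic along the genome
#'
#' @param stats A window tibble ([tajimas_d_windows()], [beta_windows()] or
#'   [balancing_scan()]).
#' @param stat Column to plot (e.g. "D", "beta", "z_D").
#' @return A ggplot object, extreme windows highlighted when flags exist.
#' @export
plot_window_stats <- function(stats, stat = "D") {
  stopifnot(stat %in% names(stats))
  flag <- paste0("extreme_", stat)
  stats$.extreme <- if (flag %in% names(stats)) stats[[flag]] else FALSE
  ggplot2::ggplot(stats,
                  ggplot2::aes(x = (.data$win_start_bp +
                                      .data$win_end_bp) / 2e6,
                               y = .data[[stat]],
                               colour = .data$.extreme)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::facet_wrap(~chrom, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "window midpoint (Mb)", y = stat) +
    ggplot2::theme_minimal()
}

#' Tidy and summary methods for run summaries
#'
#' `tidy()` returns the per-sample table; `glance()` a one-row overall
#' summary.
#'
#' @param x A `runs_summary` from [summarize_runs()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy runs_summary
#' @export
tidy.runs_summary <- function(x, ...) x$per_sample

#' @rdname tidy.runs_summary
#' @method glance runs_summary
#' @export
glance.runs_summary <- function(x, ...) {
  ps <- x$per_sample
  tibble::tibble(
    n_samples = nrow(ps),
    total_runs = sum(ps$n_runs),
    mean_runs_per_sample = mean(ps$n_runs),
    mean_total_mb = mean(ps$total_mb),
    cv_total_length = ifelse(mean(ps$total_length_bp) > 0,
                             stats::sd(ps$total_length_bp) /
                               mean(ps$total_length_bp), NA_real_),
    count_length_r = x$count_length_cor$r)
}
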