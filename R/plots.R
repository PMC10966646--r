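#' Plot a campaign's recall trajectory
#'
#' Top-k recall of the acquired set as a function of the number of compounds
#' acquired, against the random-acquisition baseline (dashed).
#'
#' @param object An `al_campaign` from [run_campaign()].
#' @param metric Which recall to draw: `"recall_top2"` or `"recall_top5"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot al_campaign
#' @export
autoplot.al_campaign <- function(object, metric = c("recall_top2", "recall_top5"), ...) {
  metric <- match.arg(metric)
  baseline <- paste0("baseline_", metric)
  df <- object$trajectory
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_acquired)) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[metric]], shape = .data$strategy)) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[baseline]]), linetype = "dashed") +
    ggplot2::labs(x = "Compounds acquired",
                  y = sprintf("Top %s%% recall", if (metric == "recall_top2") "2" else "5"),
                  shape = "Strategy",
                  title = sprintf("Protocol '%s'", object$config$protocol)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot repeated campaigns with a variability band
#'
#' Mean metric across seeds with a min-max ribbon, plus the random baseline
#' when the metric is a recall.
#'
#' @param object An `al_repeats` from [repeat_campaigns()].
#' @param metric One of the trajectory metrics (default `"recall_top2"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot al_repeats
#' @export
autoplot.al_repeats <- function(object, metric = "recall_top2", ...) {
  df <- object$summary[object$summary$metric == metric, ]
  if (nrow(df) == 0) abort(sprintf("Unknown metric '%s'.", metric))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n_acquired)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "Compounds acquired", y = metric,
                  title = sprintf("Mean and min-max band over %d seeds", length(object$seeds))) +
    ggplot2::theme_minimal()
  baseline <- object$summary[object$summary$metric == paste0("baseline_", metric), ]
  if (nrow(baseline) > 0) {
    p <- p + ggplot2::geom_line(data = baseline, ggplot2::aes(y = .data$mean),
                                linetype = "dashed")
  }
  p
}

#' Plot fold-benchmark metrics with confidence intervals
#'
#' One point per metric (across-fold mean) with its 95% confidence interval.
#'
#' @param object An `al_benchmark` from [benchmark_split()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot al_benchmark
#' @export
autoplot.al_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Across-fold mean (95% CI)",
                  title = sprintf("%d-fold benchmark, %d%% train",
                                  object$config$n_folds,
                                  round(100 * object$config$train_fraction))) +
    ggplot2::theme_minimal()
}
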