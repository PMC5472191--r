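# Figures: paired instantaneous/cumulative SRT histograms and group
# summaries.

utils::globalVariables(c("srt", "count", "outcome", "condition", "task",
                         "value", "group", "measure"))

#' SRT distributions: instantaneous and cumulative histograms
#'
#' Correct saccades are plotted upward and direction errors downward, per
#' condition, with the express epoch shaded; a cumulative panel overlays
#' the per-condition SRT ECDFs.
#'
#' @param scored Scored-trial data.frame (pooled or single subject).
#' @param bin_width Histogram bin width, ms.
#' @param express_window c(start, end) shading, ms.
#' @param xlim Latency axis range, ms.
#' @return A ggplot object.
#' @export
plot_srt_distribution <- function(scored, bin_width = 10,
                                  express_window = c(90, 140),
                                  xlim = c(0, 600)) {
  d <- scored[!is.na(scored$srt) &
                scored$outcome %in% c("correct", "direction_error"), ,
              drop = FALSE]
  edges <- seq(xlim[1], xlim[2], by = bin_width)
  d <- d[d$srt >= xlim[1] & d$srt < xlim[2], , drop = FALSE]
  d$bin <- edges[findInterval(d$srt, edges)]
  agg <- stats::aggregate(list(count = d$srt),
                          by = list(bin = d$bin, outcome = d$outcome,
                                    condition = d$condition),
                          FUN = length)
  agg$count <- ifelse(agg$outcome == "direction_error",
                      -agg$count, agg$count)
  ggplot2::ggplot(agg) +
    ggplot2::annotate("rect", xmin = express_window[1],
                      xmax = express_window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_col(ggplot2::aes(x = bin, y = count, fill = outcome),
                      width = bin_width) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~condition, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(correct = "#2b8cbe",
                                          direction_error = "#d7301f")) +
    ggplot2::labs(x = "SRT (ms)", y = "trials (errors downward)",
                  title = "SRT distributions",
                  subtitle = "shaded: express epoch") +
    ggplot2::theme_minimal()
}

#' Group summary bars for the main behavioral measures
#'
#' Group x task means with SEM error bars for mean SRT, CV of SRT,
#' direction-error percentage and anticipatory percentage.
#'
#' @param metrics Subject-metrics table.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(metrics) {
  long <- metrics_long(metrics,
                       measures = c("mean_srt", "cv_srt",
                                    "pct_direction_error",
                                    "pct_anticipatory"))
  m <- stats::reshape(long, direction = "long",
                      varying = list(c("mean_srt", "cv_srt",
                                       "pct_direction_error",
                                       "pct_anticipatory")),
                      v.names = "value",
                      times = c("mean SRT (ms)", "CV of SRT (%)",
                                "direction errors (%)",
                                "anticipatory (%)"),
                      timevar = "measure")
  agg <- stats::aggregate(value ~ group + task + measure, data = m,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) /
                                                sqrt(length(v))))
  agg <- do.call(data.frame, agg)
  names(agg)[names(agg) == "value.mean"] <- "mean"
  names(agg)[names(agg) == "value.sem"] <- "sem"
  ggplot2::ggplot(agg, ggplot2::aes(x = task, y = mean, fill = group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::facet_wrap(~measure, scales = "free_y", nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Group summaries (mean +/- SEM)") +
    ggplot2::theme_minimal()
}
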