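# Express-epoch delimitation from SRT histograms.
#
# The short-latency (express) saccade epoch is delimited from the anti-trial
# latency histogram: in each 10-ms bin a one-sided exact binomial sign test
# asks whether direction errors significantly outnumber correct anti-saccades
# (null: errors and corrects equally likely, p0 = 0.5). The epoch is the
# longest contiguous run of significant bins in the early part of the
# distribution.

#' Build an SRT histogram by condition and outcome
#'
#' Bins saccadic reaction times of scored trials into contiguous equal-width
#' bins, separately for the four series anti-correct, anti-error,
#' pro-correct, pro-error. Anticipatory and no-response trials do not enter
#' any series.
#'
#' @param scored Scored-trial data.frame ([score_session()]), or a
#'   data.frame with columns `srt` and `outcome` only (treated as anti
#'   trials).
#' @param bin_width Bin width, ms (default 10).
#' @param range Histogram range c(min, max), ms.
#' @return A list of class `srt_histogram`: `bin_edges` (length nbin+1),
#'   `counts` (nbin x 4 integer matrix, columns `anti_correct`,
#'   `anti_error`, `pro_correct`, `pro_error`), `bin_width`.
#' @export
srt_histogram <- function(scored, bin_width = 10, range = c(0, 1000)) {
  if (!"condition" %in% names(scored)) scored$condition <- "anti"
  edges <- seq(range[1], range[2], by = bin_width)
  nb <- length(edges) - 1
  series <- c("anti_correct", "anti_error", "pro_correct", "pro_error")
  counts <- matrix(0L, nb, 4, dimnames = list(NULL, series))
  pick <- list(
    anti_correct = scored$condition == "anti" & scored$outcome == "correct",
    anti_error = scored$condition == "anti" &
      scored$outcome == "direction_error",
    pro_correct = scored$condition == "pro" & scored$outcome == "correct",
    pro_error = scored$condition == "pro" &
      scored$outcome == "direction_error")
  for (s in series) {
    srt <- scored$srt[pick[[s]] & !is.na(scored$srt)]
    srt <- srt[srt >= range[1] & srt < range[2]]
    # left-closed bins [e_i, e_{i+1})
    counts[, s] <- tabulate(findInterval(srt, edges), nbins = nb)
  }
  structure(list(bin_edges = edges, counts = counts, bin_width = bin_width),
            class = "srt_histogram")
}

# one-sided exact binomial upper tail: P(X >= k), X ~ Bin(n, 0.5)
binom_tail_p_ <- function(k, n) {
  ifelse(n == 0, 1, stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Delimit the express-saccade epoch by a per-bin binomial sign test
#'
#' For every latency bin with at least `min_total` anti trials, tests
#' one-sidedly whether direction errors exceed correct anti-saccades
#' (exact binomial, p0 = 0.5). The express window is the longest contiguous
#' run of at least `min_run` significant bins with bin centers inside
#' `search_range`; its start is the left edge of the first bin in the run
#' (clipped below at `clip_lower`, the anticipatory boundary) and its end
#' the right edge of the last. Ties between equally long runs go to the
#' earlier one. When no qualifying run exists a null window (start == end)
#' is returned.
#'
#' No multiple-testing correction is applied across bins; the per-bin alpha
#' is reported as part of the result.
#'
#' @param hist An `srt_histogram` (only the anti series are used), or a
#'   scored-trial data.frame which is binned with defaults first.
#' @param alpha Per-bin significance level.
#' @param min_run Minimum run length in bins.
#' @param min_total Minimum anti trials in a bin for it to be testable.
#' @param search_range Restrict the run search to bins inside this, ms.
#' @param clip_lower Clip the window start at this anticipatory boundary,
#'   ms; `NULL` to disable.
#' @return A list of class `express_window`: `start`, `end` (ms),
#'   `p_values` (per bin), `significant` (logical per bin), `alpha`,
#'   `bin_edges`.
#' @export
detect_express_window <- function(hist, alpha = 0.05, min_run = 2,
                                  min_total = 5, search_range = c(0, 300),
                                  clip_lower = 90) {
  if (is.data.frame(hist)) hist <- srt_histogram(hist)
  stopifnot(inherits(hist, "srt_histogram"))
  err <- hist$counts[, "anti_error"]
  cor <- hist$counts[, "anti_correct"]
  if (sum(err) + sum(cor) == 0) {
    stop("histogram has no anti-trial counts")
  }
  n <- err + cor
  p <- binom_tail_p_(err, n)
  sig <- n >= min_total & p < alpha

  centers <- hist$bin_edges[-length(hist$bin_edges)] + hist$bin_width / 2
  in_search <- centers >= search_range[1] & centers <= search_range[2]
  run <- longest_true_run_(sig & in_search)

  if (is.null(run) || (run[2] - run[1] + 1) < min_run) {
    start <- end <- hist$bin_edges[1]
  } else {
    start <- hist$bin_edges[run[1]]
    end <- hist$bin_edges[run[2] + 1]
    if (!is.null(clip_lower)) start <- max(start, clip_lower)
  }
  structure(list(start = start, end = end, p_values = p, significant = sig,
                 alpha = alpha, bin_edges = hist$bin_edges),
            class = "express_window")
}

# first longest run of TRUE; c(start_index, end_index) or NULL
longest_true_run_ <- function(flag) {
  r <- rle(flag)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  c(starts[best], ends[best])
}

#' Classify scored trials into latency epochs by an express window
#'
#' Relabels the `epoch` column of scored trials using a detected express
#' window instead of the fixed 90-140 ms bounds. The anticipatory boundary
#' stays fixed at 90 ms; a window reaching below it is clipped at 90 ms with
#' a warning. The fixed 90-140 ms classification is the pipeline default;
#' window-based classification is opt-in.
#'
#' @param scored Scored-trial data.frame.
#' @param window An `express_window`, or c(start, end) in ms.
#' @return `scored` with the `epoch` column relabeled.
#' @export
classify_by_window <- function(scored, window) {
  if (inherits(window, "express_window")) {
    window <- c(window$start, window$end)
  }
  if (window[1] < 90) {
    warning("express window overlaps the anticipatory region; ",
            "clipping start at 90 ms")
    window[1] <- 90
  }
  has <- !is.na(scored$srt) & scored$outcome != "excluded"
  scored$epoch[has] <- epoch_of(scored$srt[has], express_window = window)
  scored
}
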