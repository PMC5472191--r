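# Velocity-threshold saccade detection.
#
# Velocity is estimated by a Savitzky-Golay first-derivative kernel
# (quadratic fit over an odd window; for window length 2h+1 the kernel is
# k / sum(k^2), k = -h..h, divided by the sample period). Saccades are
# maximal runs of samples whose 2-D velocity magnitude exceeds the 30 deg/s
# criterion, merged across short sub-threshold gaps and filtered by minimum
# duration and amplitude.

sg_deriv_kernel <- function(width) {
  stopifnot(width >= 3, width %% 2 == 1)
  h <- (width - 1) / 2
  k <- seq(-h, h)
  k / sum(k^2)
}

apply_kernel_ <- function(x, kern, dt_s) {
  h <- (length(kern) - 1) / 2
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n < length(kern)) return(v)
  acc <- numeric(n - 2 * h)
  for (j in seq_along(kern)) {
    acc <- acc + kern[j] * x[(j - 1) + seq_len(n - 2 * h)]
  }
  v[(h + 1):(n - h)] <- acc / dt_s
  v
}

#' Estimate eye velocity within a trial window
#'
#' Differentiates the horizontal and vertical position traces with a
#' Savitzky-Golay style smoothing-derivative kernel and returns the 2-D
#' velocity magnitude. Invalid samples propagate: every velocity estimate
#' whose kernel support touches an invalid sample is `NA`, as are the
#' half-kernel edges of the window.
#'
#' @param window A trial window (from [segment_trials()]) or any data.table
#'   with `time_ms`, `x`, `y`, `valid`.
#' @param kernel_width Odd kernel length in samples (default 5).
#' @return Numeric vector of velocity magnitudes (deg/s), same length as the
#'   window, with components `vx`, `vy` as attributes.
#' @export
compute_velocity <- function(window, kernel_width = 5) {
  if (sum(window$valid) < 5) {
    stop("window has fewer than 5 valid samples; cannot estimate velocity")
  }
  dt_s <- stats::median(diff(window$time_ms)) / 1000
  kern <- sg_deriv_kernel(kernel_width)
  vx <- apply_kernel_(window$x, kern, dt_s)
  vy <- apply_kernel_(window$y, kern, dt_s)
  v <- sqrt(vx^2 + vy^2)
  attr(v, "vx") <- vx
  attr(v, "vy") <- vy
  v
}

#' Detect saccades in a trial window by the velocity criterion
#'
#' Saccade onset and termination are the first and last samples of a maximal
#' run where eye velocity exceeds `threshold` (default 30 deg/s). Runs
#' separated by less than `merge_gap` ms are merged; events shorter than
#' `min_duration` ms or with absolute net horizontal displacement below
#' `min_amplitude` degrees are discarded. Events overlapping invalid
#' (blink/lost) samples are dropped and the window is flagged; windows with
#' more than `max_invalid_frac` invalid samples are excluded outright.
#'
#' @param window A trial window with `time_ms` re-zeroed to stimulus onset.
#' @param threshold Velocity criterion, deg/s.
#' @param merge_gap Merge events separated by less than this, ms.
#' @param min_duration Discard events shorter than this, ms.
#' @param min_amplitude Discard events with |net horizontal amplitude| below
#'   this, degrees.
#' @param kernel_width Passed to [compute_velocity()].
#' @param max_invalid_frac Exclude the window when the invalid-sample
#'   fraction exceeds this.
#' @return A list of class `saccade_detection`: `events` (data.frame with
#'   `onset`, `offset`, `latency`, `amplitude`, `peak_velocity`,
#'   `direction`; times in window ms), `flagged` (event(s) dropped over
#'   invalid samples), `excluded` (window unusable), `invalid_frac`.
#' @export
detect_saccades <- function(window, threshold = 30, merge_gap = 10,
                            min_duration = 6, min_amplitude = 0.5,
                            kernel_width = 5, max_invalid_frac = 0.30) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      latency = numeric(0), amplitude = numeric(0),
                      peak_velocity = numeric(0), direction = numeric(0))
  invalid_frac <- mean(!window$valid)
  if (invalid_frac > max_invalid_frac) {
    return(structure(list(events = empty, flagged = FALSE, excluded = TRUE,
                          invalid_frac = invalid_frac),
                     class = "saccade_detection"))
  }
  v <- compute_velocity(window, kernel_width)
  tm <- window$time_ms
  dt <- stats::median(diff(tm))

  above <- !is.na(v) & v > threshold
  runs <- run_bounds_(above)
  if (nrow(runs) > 1 && merge_gap > 0) {
    runs <- merge_runs_(runs, tm, merge_gap)
  }
  # events touching invalid data are untrustworthy: dilate the invalid mask
  # by the kernel half-width so blink-truncated fragments are caught too
  h <- (kernel_width - 1) / 2 + 1
  invalid <- !window$valid
  if (any(invalid)) {
    idx <- which(invalid)
    near <- unique(pmin(pmax(rep(idx, each = 2 * h + 1) +
                               rep(-h:h, length(idx)), 1), length(invalid)))
    invalid[near] <- TRUE
  }
  flagged <- FALSE
  keep <- logical(nrow(runs))
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    if (any(invalid[a:b])) { flagged <- TRUE; next }
    dur <- tm[b] - tm[a] + dt      # run occupies its samples' periods
    amp <- window$x[b] - window$x[a]
    if (dur < min_duration || abs(amp) < min_amplitude) next
    keep[i] <- TRUE
    out[[i]] <- data.frame(
      onset = tm[a], offset = tm[b], latency = tm[a],
      amplitude = amp,
      peak_velocity = max(v[a:b], na.rm = TRUE),
      direction = sign(amp))
  }
  events <- if (any(keep)) do.call(rbind, out[keep]) else empty
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, flagged = flagged, excluded = FALSE,
                 invalid_frac = invalid_frac),
            class = "saccade_detection")
}

run_bounds_ <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

merge_runs_ <- function(runs, tm, merge_gap) {
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- tm[runs$start[i]] - tm[merged$end[nrow(merged)]]
    if (gap < merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged
}

#' Detect saccades in every trial window of a session
#'
#' @param windows A `trial_windows` list from [segment_trials()].
#' @param ... Passed to [detect_saccades()].
#' @return A list of `saccade_detection` objects, one per window, each
#'   carrying the window's `trial_id`, `condition`, `side` attributes.
#' @export
detect_session <- function(windows, ...) {
  lapply(windows, function(w) {
    d <- detect_saccades(w, ...)
    attr(d, "trial_id") <- attr(w, "trial_id")
    attr(d, "condition") <- attr(w, "condition")
    attr(d, "side") <- attr(w, "side")
    d
  })
}
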