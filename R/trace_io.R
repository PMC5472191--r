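# Reading/writing the package's open CSV dialects and trial segmentation.
#
# Gaze dialect: one header row, columns time_ms, x_deg, y_deg, valid
# (degree-valued files) or time_ms, x_px, y_px, valid (pixel-valued files,
# which require a screen geometry on read). `valid` is 0/1; invalid samples
# carry NaN positions. Event dialect: one row per trial with trial_id,
# condition, side, fixation_on, gap_on, stimulus_on, stimulus_off (ms).

#' Screen geometry for pixel-to-degree conversion
#'
#' Defaults: 1280 x 1024 px display subtending 32 x 26 degrees at 60 cm.
#'
#' @param resolution_px c(width, height), pixels.
#' @param extent_deg c(width, height), degrees of visual angle.
#' @param viewing_distance cm.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(resolution_px = c(1280, 1024),
                            extent_deg = c(32, 26),
                            viewing_distance = 60) {
  stopifnot(length(resolution_px) == 2, length(extent_deg) == 2,
            all(resolution_px > 0), all(extent_deg > 0),
            viewing_distance > 0)
  structure(list(resolution_px = resolution_px, extent_deg = extent_deg,
                 viewing_distance = viewing_distance),
            class = "screen_geometry")
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' The origin is the screen center (the fixation point); x grows rightward,
#' y grows upward (screen pixel rows grow downward, so y is flipped). The
#' default `"linear"` dialect maps degrees proportionally to pixels
#' (`deg = px_offset * extent_deg / resolution_px`); the `"tangent"` dialect
#' converts through the true viewing angle, using the physical screen size
#' implied by the extent and viewing distance.
#'
#' @param x_px,y_px Pixel coordinates.
#' @param geometry A [screen_geometry()].
#' @param method `"linear"` (default) or `"tangent"`.
#' @return A list with numeric vectors `x_deg`, `y_deg`.
#' @examples
#' px_to_deg(640, 512)              # screen center -> (0, 0)
#' px_to_deg(640 + 400, 512)$x_deg  # +10 deg with the default geometry
#' @export
px_to_deg <- function(x_px, y_px, geometry = screen_geometry(),
                      method = c("linear", "tangent")) {
  method <- match.arg(method)
  cx <- geometry$resolution_px[1] / 2
  cy <- geometry$resolution_px[2] / 2
  if (method == "linear") {
    list(x_deg = (x_px - cx) * geometry$extent_deg[1] /
           geometry$resolution_px[1],
         y_deg = (cy - y_px) * geometry$extent_deg[2] /
           geometry$resolution_px[2])
  } else {
    d <- geometry$viewing_distance
    half_w <- d * tan(geometry$extent_deg[1] / 2 * pi / 180)
    half_h <- d * tan(geometry$extent_deg[2] / 2 * pi / 180)
    cm_x <- (x_px - cx) / cx * half_w
    cm_y <- (cy - y_px) / cy * half_h
    list(x_deg = atan2(cm_x, d) * 180 / pi,
         y_deg = atan2(cm_y, d) * 180 / pi)
  }
}

#' Read a gaze recording from CSV
#'
#' Accepts the degree dialect (`time_ms,x_deg,y_deg,valid`) or the pixel
#' dialect (`time_ms,x_px,y_px,valid`); pixel files require `geometry` and
#' are converted with [px_to_deg()]. Invalid samples (valid = 0) are kept
#' with `NA` positions. Timestamps must be uniform within a tolerance of one
#' sample period.
#'
#' @param path CSV file path.
#' @param geometry A [screen_geometry()]; required for pixel files.
#' @param method Pixel conversion dialect, see [px_to_deg()].
#' @return A data.table with columns `time_ms`, `x`, `y`, `valid` (degrees)
#'   and attribute `sample_rate` (Hz).
#' @export
read_gaze <- function(path, geometry = NULL,
                      method = c("linear", "tangent")) {
  dat <- data.table::fread(path, na.strings = c("NA", "NaN", "nan"))
  cols <- names(dat)
  if (!"time_ms" %in% cols || !"valid" %in% cols) {
    stop("gaze file lacks required columns (time_ms, valid): ", path)
  }
  if (all(c("x_deg", "y_deg") %in% cols)) {
    out <- data.table::data.table(time_ms = dat$time_ms,
                                  x = dat$x_deg, y = dat$y_deg)
  } else if (all(c("x_px", "y_px") %in% cols)) {
    if (is.null(geometry)) {
      stop("pixel-valued gaze file requires a screen geometry: ", path)
    }
    dd <- px_to_deg(dat$x_px, dat$y_px, geometry, method)
    out <- data.table::data.table(time_ms = dat$time_ms,
                                  x = dd$x_deg, y = dd$y_deg)
  } else {
    stop("gaze file must have x_deg/y_deg or x_px/y_px columns: ", path)
  }
  out$valid <- as.logical(dat$valid)
  out$x[!out$valid] <- NA_real_
  out$y[!out$valid] <- NA_real_
  # non-finite positions are treated as invalid even if flagged valid
  out$valid[!is.finite(out$x) | !is.finite(out$y)] <- FALSE

  dts <- diff(out$time_ms)
  if (length(dts) == 0) stop("gaze file has fewer than 2 samples: ", path)
  period <- stats::median(dts)
  bad <- which(abs(dts - period) > period)
  if (length(bad) > 0) {
    stop(sprintf(
      "non-uniform sampling: interval after t = %g ms is %g ms (expected %g)",
      out$time_ms[bad[1]], dts[bad[1]], period))
  }
  data.table::setattr(out, "sample_rate", 1000 / period)
  out
}

#' Write a gaze recording to CSV (degree dialect)
#'
#' Positions are written with 6 significant decimals; invalid samples get
#' NaN positions and valid = 0. [read_gaze()] on the result reproduces the
#' recording to that precision.
#'
#' @param gaze A gaze data.table (`time_ms`, `x`, `y`, `valid`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(gaze, path) {
  out <- data.table::data.table(
    time_ms = gaze$time_ms,
    x_deg = round(gaze$x, 6),
    y_deg = round(gaze$y, 6),
    valid = as.integer(gaze$valid))
  data.table::fwrite(out, path, na = "NaN")
  invisible(path)
}

#' Read / write a trial event log
#'
#' One row per trial: `trial_id`, `condition` (pro/anti), `side`
#' (left/right), `fixation_on`, `gap_on`, `stimulus_on`, `stimulus_off`
#' (ms, session clock). Ordering constraints are checked on read.
#'
#' @param path CSV file path.
#' @return `read_events`: a data.table of trial events.
#' @export
read_events <- function(path) {
  ev <- data.table::fread(path)
  need <- c("trial_id", "condition", "side", "fixation_on", "gap_on",
            "stimulus_on", "stimulus_off")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0) {
    stop("event file lacks columns: ", paste(miss, collapse = ", "))
  }
  bad <- with(ev, !(fixation_on < gap_on & gap_on < stimulus_on &
                      stimulus_on < stimulus_off))
  if (any(bad)) {
    stop("event timestamps out of order for trial(s): ",
         paste(ev$trial_id[bad], collapse = ", "))
  }
  ev
}

#' @rdname read_events
#' @param events Event data.table to write.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' Segment a continuous recording into per-trial windows
#'
#' Cuts the recording into one window per trial spanning
#' `[fixation_on, stimulus_off]` and re-zeroes each window's timebase to
#' stimulus onset, the reference for saccadic reaction time. Each window
#' carries the trial's id, condition and side as attributes-like columns.
#'
#' @param gaze A gaze recording (from [read_gaze()] or
#'   [generate_session()]).
#' @param events A trial event log.
#' @return A list of class `trial_windows`: each element a data.table with
#'   `time_ms` (0 = stimulus onset), `x`, `y`, `valid`, plus attributes
#'   `trial_id`, `condition`, `side`, `sample_rate`.
#' @export
segment_trials <- function(gaze, events) {
  t0 <- gaze$time_ms[1]
  period <- stats::median(diff(gaze$time_ms))
  # the final boundary sample may fall exactly one period past the trace
  t_end <- gaze$time_ms[nrow(gaze)] + period
  out_of_range <- events$fixation_on < t0 | events$stimulus_off > t_end
  if (any(out_of_range)) {
    stop("trial(s) outside the recording: ",
         paste(events$trial_id[out_of_range], collapse = ", "))
  }
  windows <- vector("list", nrow(events))
  tm <- gaze$time_ms
  n <- length(tm)
  for (i in seq_len(nrow(events))) {
    # uniform sampling lets windows be indexed arithmetically
    lo <- events$fixation_on[i] - period / 2
    hi <- events$stimulus_off[i] + period / 2
    i0 <- max(1L, ceiling((lo - tm[1]) / period) + 1L)
    i1 <- min(n, floor((hi - tm[1]) / period) + 1L)
    w <- gaze[i0:i1, ]
    w$time_ms <- w$time_ms - events$stimulus_on[i]
    data.table::setattr(w, "trial_id", events$trial_id[i])
    data.table::setattr(w, "condition", events$condition[i])
    data.table::setattr(w, "side", events$side[i])
    data.table::setattr(w, "sample_rate", 1000 / period)
    windows[[i]] <- w
  }
  structure(windows, class = "trial_windows")
}
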