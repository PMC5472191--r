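# Trial scoring: from detected saccades to outcome labels.
#
# The first saccade with onset at or after stimulus appearance defines the
# saccadic reaction time (SRT) and response direction. Trials are correct if
# that saccade goes toward the stimulus (pro trials) or away from it (anti
# trials), direction errors otherwise; saccades launched before visual
# information can reach the oculomotor system (SRT < 90 ms) are anticipatory
# regardless of direction. Latency epochs: anticipatory [0, 90) ms, express
# [90, 140] ms, regular (140, 1000] ms.

#' Assign a latency epoch to SRT values
#'
#' @param srt Numeric vector of saccadic reaction times, ms.
#' @param express_window c(start, end) of the express epoch, ms; the
#'   anticipatory boundary is fixed at the window start's lower limit of
#'   90 ms.
#' @return Character vector: `"anticipatory"`, `"express"`, `"regular"`, or
#'   `NA` for missing SRT.
#' @export
epoch_of <- function(srt, express_window = c(90, 140)) {
  ifelse(is.na(srt), NA_character_,
  ifelse(srt < 90, "anticipatory",
  ifelse(srt >= express_window[1] & srt <= express_window[2], "express",
         "regular")))
}

#' Score one trial from its detected saccades
#'
#' @param events Saccade event data.frame (from [detect_saccades()]),
#'   times relative to stimulus onset.
#' @param condition `"pro"` or `"anti"`.
#' @param side Stimulus side, `"left"` or `"right"`.
#' @param stimulus_eccentricity Horizontal stimulus eccentricity, degrees.
#' @param response_window c(min, max) onset for a qualifying response, ms;
#'   the default `c(0, 1000)` accepts saccades from stimulus appearance to
#'   stimulus offset. A first saccade later than the window maximum makes
#'   the trial `excluded`; no saccade at all is `no_response`.
#' @param excluded Set `TRUE` when the detection stage excluded the window
#'   (e.g. too many invalid samples).
#' @param correction_tolerance Landing tolerance around the required final
#'   location for a corrective saccade, degrees.
#' @return A one-row data.frame: `condition`, `side`, `srt`, `outcome`
#'   (`correct` / `direction_error` / `anticipatory` / `no_response` /
#'   `excluded`), `epoch`, `first_direction`, `corrected`, `n_saccades`.
#' @export
score_trial <- function(events, condition, side,
                        stimulus_eccentricity = 10,
                        response_window = c(0, 1000),
                        excluded = FALSE,
                        correction_tolerance = 3) {
  res <- data.frame(condition = condition, side = side,
                    srt = NA_real_, outcome = "no_response",
                    epoch = "none", first_direction = NA_real_,
                    corrected = FALSE, n_saccades = 0L,
                    stringsAsFactors = FALSE)
  if (excluded) {
    res$outcome <- "excluded"
    return(res)
  }
  cand <- events[events$onset >= response_window[1], , drop = FALSE]
  res$n_saccades <- nrow(cand)
  if (nrow(cand) == 0) return(res)

  first <- cand[1, ]
  res$srt <- first$onset
  res$first_direction <- first$direction
  if (first$onset > response_window[2]) {
    res$outcome <- "excluded"
    res$epoch <- "none"
    return(res)
  }
  side_sign <- if (side == "right") 1 else -1
  correct_dir <- if (condition == "pro") side_sign else -side_sign
  res$epoch <- epoch_of(first$onset)
  if (res$epoch == "anticipatory") {
    # direction is at chance before visual information arrives
    res$outcome <- "anticipatory"
  } else if (first$direction == correct_dir) {
    res$outcome <- "correct"
  } else {
    res$outcome <- "direction_error"
    res$corrected <- detect_correction(
      cand, first_index = 1, correct_dir = correct_dir,
      target = correct_dir * stimulus_eccentricity,
      tolerance = correction_tolerance)
  }
  res
}

#' Identify a corrective saccade after a direction error
#'
#' A direction error counts as corrected when a later saccade reverses
#' direction and the cumulative horizontal displacement from the error
#' saccade's start lands within `tolerance` degrees of the required final
#' location (the stimulus for pro trials, its mirror for anti trials).
#'
#' @param events Saccade events of the trial (onset order), relative to
#'   stimulus onset.
#' @param first_index Row index of the erroneous primary saccade.
#' @param correct_dir Required direction, -1 or +1.
#' @param target Required final horizontal position, degrees (from center).
#' @param tolerance Landing tolerance, degrees.
#' @return Logical.
#' @export
detect_correction <- function(events, first_index = 1, correct_dir,
                              target, tolerance = 3) {
  if (nrow(events) <= first_index) return(FALSE)
  later <- events[(first_index + 1):nrow(events), , drop = FALSE]
  # eye starts a response at the center, so position after each saccade is
  # the running sum of signed amplitudes
  pos <- cumsum(events$amplitude)[-seq_len(first_index)]
  rev_dir <- later$direction == correct_dir
  landed <- abs(pos - target) <= tolerance
  any(rev_dir & landed)
}

#' Score every trial of a session
#'
#' Runs [score_trial()] over per-window detection results, carrying over each
#' window's trial metadata.
#'
#' @param detections List of `saccade_detection` results from
#'   [detect_session()].
#' @param events Trial event log (for eccentricity-independent metadata);
#'   optional if detections carry attributes.
#' @param stimulus_eccentricity Degrees.
#' @param ... Passed to [score_trial()].
#' @return A data.frame of scored trials, one row per trial, with
#'   `trial_id` first.
#' @export
score_session <- function(detections, events = NULL,
                          stimulus_eccentricity = 10, ...) {
  rows <- lapply(seq_along(detections), function(i) {
    d <- detections[[i]]
    r <- score_trial(d$events,
                     condition = attr(d, "condition"),
                     side = attr(d, "side"),
                     stimulus_eccentricity = stimulus_eccentricity,
                     excluded = d$excluded, ...)
    r$trial_id <- attr(d, "trial_id")
    r$flagged <- d$flagged
    r
  })
  out <- do.call(rbind, rows)
  out[, c("trial_id", setdiff(names(out), "trial_id"))]
}

#' Score trials directly from generator ground truth
#'
#' Bypasses trace synthesis and detection, mapping a ground-truth table to
#' the scored-trial schema. Used for statistical calibration studies where
#' thousands of sessions are needed and the detector is not under test.
#'
#' @param truth Ground-truth table from [generate_session()].
#' @return A scored-trial data.frame as from [score_session()].
#' @export
score_from_truth <- function(truth) {
  data.frame(trial_id = truth$trial_id,
             condition = truth$condition,
             side = truth$side,
             srt = truth$srt,
             outcome = truth$outcome,
             epoch = truth$epoch,
             first_direction = truth$first_direction,
             corrected = truth$corrected,
             n_saccades = ifelse(is.na(truth$srt), 0L,
                                 1L + as.integer(truth$corrected)),
             flagged = FALSE,
             stringsAsFactors = FALSE)
}
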