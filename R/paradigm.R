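#' Paradigm configuration for the interleaved pro-/anti-saccade gap task
#'
#' Describes the timing, geometry and trial structure of a recording session.
#' Defaults reproduce the standard gap paradigm this package analyses:
#' 1000 ms central fixation, a 200 ms gap, then a peripheral stimulus at
#' 10 degrees horizontal eccentricity shown for 1000 ms; two blocks of 120
#' pseudorandomly interleaved pro- and anti-saccade trials recorded at 500 Hz
#' on a 1280 x 1024 px screen subtending 32 x 26 degrees at 60 cm.
#'
#' Within a session trials are split 50/50 between pro and anti instructions
#' and 50/50 between left and right stimulus locations, pseudorandomly
#' interleaved.
#'
#' @param fixation_duration Central fixation duration, ms.
#' @param gap_duration Gap between fixation offset and stimulus onset, ms.
#' @param stimulus_duration Peripheral stimulus duration, ms.
#' @param stimulus_eccentricity Horizontal stimulus eccentricity, degrees.
#' @param trials_per_block Trials in one block.
#' @param n_blocks Number of blocks.
#' @param sample_rate Eye-tracker sampling rate, Hz.
#' @param screen_px Screen resolution, c(width, height), pixels.
#' @param screen_deg Screen extent, c(width, height), degrees of visual angle.
#' @param viewing_distance Eye-to-screen distance, cm.
#' @return An object of class `paradigm_config`.
#' @examples
#' p <- paradigm_config()
#' p$trials_per_block * p$n_blocks  # 240 trials per session
#' @export
paradigm_config <- function(fixation_duration = 1000,
                            gap_duration = 200,
                            stimulus_duration = 1000,
                            stimulus_eccentricity = 10,
                            trials_per_block = 120,
                            n_blocks = 2,
                            sample_rate = 500,
                            screen_px = c(1280, 1024),
                            screen_deg = c(32, 26),
                            viewing_distance = 60) {
  stopifnot(
    fixation_duration > 0, gap_duration > 0, stimulus_duration > 0,
    stimulus_eccentricity > 0, trials_per_block >= 1, n_blocks >= 1,
    sample_rate > 0, length(screen_px) == 2L, length(screen_deg) == 2L,
    all(screen_px > 0), all(screen_deg > 0), viewing_distance > 0
  )
  cfg <- list(
    fixation_duration = fixation_duration,
    gap_duration = gap_duration,
    stimulus_duration = stimulus_duration,
    stimulus_eccentricity = stimulus_eccentricity,
    trials_per_block = as.integer(trials_per_block),
    n_blocks = as.integer(n_blocks),
    sample_rate = sample_rate,
    screen_px = screen_px,
    screen_deg = screen_deg,
    viewing_distance = viewing_distance
  )
  # gap not an integer number of samples is legal but worth a note
  dt <- 1000 / sample_rate
  if (abs(gap_duration / dt - round(gap_duration / dt)) > 1e-9) {
    message("gap_duration is not an integer number of samples at ",
            sample_rate, " Hz; event times are rounded to the sample grid")
  }
  structure(cfg, class = "paradigm_config")
}

#' Trial duration (fixation + gap + stimulus) in ms
#' @param paradigm A `paradigm_config`.
#' @return Duration of one trial, ms.
#' @export
trial_duration <- function(paradigm) {
  paradigm$fixation_duration + paradigm$gap_duration + paradigm$stimulus_duration
}

#' Behavioral profile driving the synthetic latency/outcome mixture
#'
#' Per-condition mixture over three latency components: anticipatory saccades
#' (uniform on [0, 90) ms, direction at chance), express saccades (truncated
#' normal inside the express epoch) and regular-latency saccades (truncated
#' normal above 140 ms). The remaining probability mass after anticipatory,
#' express and no-response is the regular component. Direction errors on anti
#' trials are drawn per epoch; a fraction `correction_prob` of errors is
#' followed by a corrective saccade to the mirror location.
#'
#' Defaults describe a healthy-control-like observer: moderate express rates,
#' low regular-latency anti errors, few anticipatory saccades. See
#' [patient_profile()] for an observer with impaired saccade inhibition.
#'
#' @param anticipatory_rate_pro,anticipatory_rate_anti Probability of an
#'   anticipatory saccade per trial, by condition.
#' @param express_weight_pro,express_weight_anti Probability of an express
#'   saccade per trial, by condition.
#' @param regular_latency_mean_pro,regular_latency_sd_pro Regular-latency
#'   component, pro trials, ms.
#' @param regular_latency_mean_anti,regular_latency_sd_anti Same, anti trials.
#' @param express_latency_mean,express_latency_sd Express component, ms.
#' @param direction_error_prob_express Probability that an express-epoch anti
#'   saccade goes toward the stimulus (a direction error).
#' @param direction_error_prob_regular Same for regular-latency anti saccades.
#' @param direction_error_prob_pro Probability of a direction error on pro
#'   trials (away from the stimulus); small in practice.
#' @param correction_prob Probability that a direction error is followed by a
#'   corrective saccade to the correct location.
#' @param no_response_prob Probability that no saccade is made in the response
#'   window.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(anticipatory_rate_pro = 0.10,
                             anticipatory_rate_anti = 0.08,
                             express_weight_pro = 0.25,
                             express_weight_anti = 0.12,
                             regular_latency_mean_pro = 210,
                             regular_latency_sd_pro = 45,
                             regular_latency_mean_anti = 270,
                             regular_latency_sd_anti = 60,
                             express_latency_mean = 115,
                             express_latency_sd = 12,
                             direction_error_prob_express = 0.13,
                             direction_error_prob_regular = 0.18,
                             direction_error_prob_pro = 0.02,
                             correction_prob = 0.85,
                             no_response_prob = 0.01) {
  pr <- c(anticipatory_rate_pro, anticipatory_rate_anti,
          express_weight_pro, express_weight_anti,
          direction_error_prob_express, direction_error_prob_regular,
          direction_error_prob_pro, correction_prob, no_response_prob)
  if (any(pr < 0 | pr > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (anticipatory_rate_pro + express_weight_pro + no_response_prob > 1 ||
      anticipatory_rate_anti + express_weight_anti + no_response_prob > 1) {
    stop("mixture weights (anticipatory + express + no-response) exceed 1 ",
         "for at least one condition")
  }
  stopifnot(regular_latency_sd_pro > 0, regular_latency_sd_anti > 0,
            express_latency_sd > 0)
  structure(list(
    anticipatory_rate_pro = anticipatory_rate_pro,
    anticipatory_rate_anti = anticipatory_rate_anti,
    express_weight_pro = express_weight_pro,
    express_weight_anti = express_weight_anti,
    regular_latency_mean_pro = regular_latency_mean_pro,
    regular_latency_sd_pro = regular_latency_sd_pro,
    regular_latency_mean_anti = regular_latency_mean_anti,
    regular_latency_sd_anti = regular_latency_sd_anti,
    express_latency_mean = express_latency_mean,
    express_latency_sd = express_latency_sd,
    direction_error_prob_express = direction_error_prob_express,
    direction_error_prob_regular = direction_error_prob_regular,
    direction_error_prob_pro = direction_error_prob_pro,
    correction_prob = correction_prob,
    no_response_prob = no_response_prob
  ), class = "behavior_profile")
}

#' Preset behavioral profiles
#'
#' `control_profile()` is the [behavior_profile()] default. `patient_profile()`
#' describes an observer with impaired voluntary saccade inhibition: a much
#' higher regular-latency anti-saccade error rate, more anticipatory saccades
#' in anti trials, and slower, more variable regular latencies.
#'
#' @param ... Overrides passed on to [behavior_profile()].
#' @return A `behavior_profile`.
#' @export
control_profile <- function(...) behavior_profile(...)

#' @rdname control_profile
#' @export
patient_profile <- function(...) {
  defaults <- list(
    anticipatory_rate_pro = 0.10,
    anticipatory_rate_anti = 0.16,
    express_weight_pro = 0.22,
    express_weight_anti = 0.10,
    regular_latency_mean_pro = 230,
    regular_latency_sd_pro = 60,
    regular_latency_mean_anti = 310,
    regular_latency_sd_anti = 85,
    direction_error_prob_express = 0.11,
    direction_error_prob_regular = 0.48,
    no_response_prob = 0.02
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(behavior_profile, args)
}

#' Saccade kinematics for the synthetic trace generator
#'
#' Saccades are synthesized as minimum-jerk position profiles whose duration
#' follows a linear amplitude-duration law and whose peak velocity is capped
#' by a saturating main-sequence curve `vmax * (1 - exp(-A / scale))`. The
#' analytic peak velocity of a minimum-jerk movement of amplitude A and
#' duration D is `1.875 * A / D`; when that exceeds the main-sequence cap the
#' duration is stretched so the peak sits on the cap. The resulting peak
#' velocity is a monotonically increasing, saturating function of amplitude.
#'
#' @param main_sequence_vmax Asymptotic peak velocity, deg/s.
#' @param main_sequence_scale Amplitude scale of the saturating curve, deg.
#' @param duration_slope Amplitude-duration slope, ms per degree.
#' @param duration_intercept Amplitude-duration intercept, ms.
#' @param position_noise_sd White position noise per sample, degrees (RMS); video eye trackers typically show 0.03-0.08.
#' @param blink_rate Expected blinks per trial (validity dropouts).
#' @param drift_sd Slow fixation drift over one trial (random walk total SD),
#'   degrees.
#' @return An object of class `kinematic_model`.
#' @export
kinematic_model <- function(main_sequence_vmax = 500,
                            main_sequence_scale = 5,
                            duration_slope = 2.2,
                            duration_intercept = 21,
                            position_noise_sd = 0.05,
                            blink_rate = 0.05,
                            drift_sd = 0.10) {
  stopifnot(main_sequence_vmax > 0, main_sequence_scale > 0,
            duration_slope > 0, duration_intercept > 0,
            position_noise_sd >= 0, blink_rate >= 0, drift_sd >= 0)
  structure(list(
    main_sequence_vmax = main_sequence_vmax,
    main_sequence_scale = main_sequence_scale,
    duration_slope = duration_slope,
    duration_intercept = duration_intercept,
    position_noise_sd = position_noise_sd,
    blink_rate = blink_rate,
    drift_sd = drift_sd
  ), class = "kinematic_model")
}

#' Main-sequence peak velocity and duration for a saccade amplitude
#'
#' Returns the analytic peak velocity (deg/s) and effective duration (ms) the
#' generator uses for a saccade of the given amplitude, after applying the
#' main-sequence velocity cap. These are the values the detector is expected
#' to recover on noiseless traces.
#'
#' @param amplitude Saccade amplitude, degrees (positive).
#' @param kinematics A [kinematic_model()].
#' @return A list with elements `peak_velocity` (deg/s) and `duration` (ms).
#' @export
main_sequence <- function(amplitude, kinematics = kinematic_model()) {
  stopifnot(all(amplitude > 0))
  d0 <- kinematics$duration_intercept + kinematics$duration_slope * amplitude
  vp_jerk <- 1.875 * amplitude / (d0 / 1000)        # min-jerk peak, deg/s
  vp_cap <- kinematics$main_sequence_vmax *
    (1 - exp(-amplitude / kinematics$main_sequence_scale))
  vp <- pmin(vp_jerk, vp_cap)
  list(peak_velocity = vp, duration = 1.875 * amplitude / vp * 1000)
}
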