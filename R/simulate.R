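# Synthetic gaze-trace and cohort generator.
#
# Latencies are drawn per trial from a three-component mixture (anticipatory /
# express / regular); saccades are rendered as minimum-jerk position profiles
# obeying the kinematic model's main sequence. Ground-truth onset and offset
# times use the same operational definition as the detector: the time at
# which the analytic velocity profile crosses the 30 deg/s criterion.

# minimum-jerk position shape on s in [0, 1]
mj_shape <- function(s) s^3 * (10 - 15 * s + 6 * s^2)

# fraction of movement duration at which the analytic min-jerk velocity
# profile v(s) = vpeak * 16 s^2 (1 - s)^2 crosses `thr` on the way up
mj_crossing_frac <- function(vpeak, thr = 30) {
  q <- sqrt(thr / (16 * vpeak))
  ifelse(4 * q >= 1, 0.5, (1 - sqrt(pmax(0, 1 - 4 * q))) / 2)
}

# inverse-CDF truncated normal draw
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, pmin(plo, phi - 1e-12), phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

# run code under a given seed, restoring the caller's RNG state afterwards
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# balanced pseudorandom interleave of condition x side within each block
interleave_trials_ <- function(paradigm) {
  combos <- expand.grid(condition = c("pro", "anti"),
                        side = c("left", "right"),
                        stringsAsFactors = FALSE)
  out <- vector("list", paradigm$n_blocks)
  for (b in seq_len(paradigm$n_blocks)) {
    idx <- rep_len(sample.int(4L), paradigm$trials_per_block)
    # rep_len of a shuffled base keeps the split as even as the count allows
    idx <- sample(idx)
    out[[b]] <- combos[idx, , drop = FALSE]
  }
  do.call(rbind, out)
}

# vectorized per-trial latency/outcome draws from the behavioral mixture
draw_outcomes_ <- function(condition, profile, stimulus_duration) {
  n <- length(condition)
  anti <- condition == "anti"
  p_ant <- ifelse(anti, profile$anticipatory_rate_anti,
                  profile$anticipatory_rate_pro)
  p_exp <- ifelse(anti, profile$express_weight_anti,
                  profile$express_weight_pro)
  p_nr <- profile$no_response_prob

  u <- stats::runif(n)
  component <- ifelse(u < p_nr, "none",
               ifelse(u < p_nr + p_ant, "anticipatory",
               ifelse(u < p_nr + p_ant + p_exp, "express", "regular")))

  srt <- rep(NA_real_, n)
  i <- component == "anticipatory"
  srt[i] <- stats::runif(sum(i), 0, 90)
  i <- component == "express"
  srt[i] <- rtruncnorm_(sum(i), profile$express_latency_mean,
                        profile$express_latency_sd, 90, 140)
  i <- component == "regular" & anti
  srt[i] <- rtruncnorm_(sum(i), profile$regular_latency_mean_anti,
                        profile$regular_latency_sd_anti, 140,
                        stimulus_duration)
  i <- component == "regular" & !anti
  srt[i] <- rtruncnorm_(sum(i), profile$regular_latency_mean_pro,
                        profile$regular_latency_sd_pro, 140,
                        stimulus_duration)

  p_err <- ifelse(!anti, profile$direction_error_prob_pro,
           ifelse(component == "express", profile$direction_error_prob_express,
                  profile$direction_error_prob_regular))
  is_error <- stats::runif(n) < p_err & component %in% c("express", "regular")
  # anticipatory saccade direction is at chance: toward or away 50/50
  anticip_toward <- stats::runif(n) < 0.5
  wants_corr <- is_error & stats::runif(n) < profile$correction_prob

  data.frame(component = component, srt = srt, is_error = is_error,
             anticip_toward = anticip_toward, wants_corr = wants_corr,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic recording session
#'
#' Simulates a full session of the interleaved pro-/anti-saccade gap task:
#' a continuous monocular gaze trace, the trial event log, and a ground-truth
#' table recording, for every trial, the true saccadic reaction time,
#' direction, outcome and kinematics of the response. Ground-truth onsets and
#' offsets are the times at which the analytic velocity profile of the
#' rendered saccade crosses 30 deg/s, i.e. the same operational definition
#' the velocity-threshold detector applies to the trace.
#'
#' Between trials the eye is returned to the center by a refixation saccade
#' early in the next trial's fixation period; refixations are part of the
#' trace but not of the ground truth, and fall before the scoring window.
#' Blinks appear as runs of invalid samples with undefined position, placed
#' in the fixation period.
#'
#' @param paradigm A [paradigm_config()].
#' @param profile A [behavior_profile()].
#' @param kinematics A [kinematic_model()].
#' @param seed Integer seed; identical inputs give identical output.
#' @param trace If `FALSE`, skip gaze-trace synthesis and return only the
#'   event log and ground truth (fast path for statistical calibration).
#' @return A list of class `session` with elements `gaze` (data.table:
#'   `time_ms`, `x`, `y`, `valid`; degrees; `NA` position when invalid),
#'   `events` (one row per trial: `trial_id`, `condition`, `side`,
#'   `fixation_on`, `gap_on`, `stimulus_on`, `stimulus_off`, ms), and
#'   `truth` (one row per trial with true SRT, outcome, epoch, direction,
#'   onset/offset, amplitude, peak velocity, correction fields).
#' @examples
#' s <- generate_session(paradigm_config(trials_per_block = 4, n_blocks = 1),
#'                       seed = 1)
#' nrow(s$events)
#' @export
generate_session <- function(paradigm = paradigm_config(),
                             profile = behavior_profile(),
                             kinematics = kinematic_model(),
                             seed = 1L,
                             trace = TRUE) {
  stopifnot(inherits(paradigm, "paradigm_config"),
            inherits(profile, "behavior_profile"),
            inherits(kinematics, "kinematic_model"))
  with_seed_(seed, generate_session_(paradigm, profile, kinematics, trace))
}

generate_session_ <- function(paradigm, profile, kinematics, trace) {
  dt <- 1000 / paradigm$sample_rate
  trial_ms <- trial_duration(paradigm)
  n_per_trial <- round(trial_ms / dt)
  n_trials <- paradigm$trials_per_block * paradigm$n_blocks
  ecc <- paradigm$stimulus_eccentricity
  stim_local <- paradigm$fixation_duration + paradigm$gap_duration

  design <- interleave_trials_(paradigm)
  trial_start <- (seq_len(n_trials) - 1) * trial_ms
  events <- data.table::data.table(
    trial_id = seq_len(n_trials),
    condition = design$condition,
    side = design$side,
    fixation_on = trial_start,
    gap_on = trial_start + paradigm$fixation_duration,
    stimulus_on = trial_start + stim_local,
    stimulus_off = trial_start + stim_local + paradigm$stimulus_duration
  )

  draws <- draw_outcomes_(design$condition, profile,
                          paradigm$stimulus_duration)
  side_sign <- ifelse(design$side == "right", 1, -1)
  correct_dir <- ifelse(design$condition == "pro", side_sign, -side_sign)
  first_dir <- ifelse(draws$component == "anticipatory",
                      ifelse(draws$anticip_toward, side_sign, -side_sign),
                      ifelse(draws$is_error, -correct_dir, correct_dir))
  first_dir[draws$component == "none"] <- NA_real_

  outcome <- ifelse(draws$component == "none", "no_response",
             ifelse(draws$component == "anticipatory", "anticipatory",
             ifelse(draws$is_error, "direction_error", "correct")))
  epoch <- ifelse(draws$component == "none", "none", draws$component)

  # response kinematics: target at +/- eccentricity with endpoint noise
  endpoint <- first_dir * ecc + stats::rnorm(n_trials, 0, 0.5)
  endpoint[is.na(first_dir)] <- 0
  amp <- endpoint                           # responses launch from center
  has_sacc <- !is.na(draws$srt)
  ms <- main_sequence(pmax(abs(amp), 0.5), kinematics)
  vpeak <- ms$peak_velocity
  dur <- ms$duration
  s_c <- mj_crossing_frac(vpeak)
  # drawn SRT is the operational (30 deg/s) onset; movement begins earlier
  move_start <- draws$srt - s_c * dur
  onset <- draws$srt
  offset <- move_start + (1 - s_c) * dur

  # corrective saccades after direction errors: back across to the correct
  # endpoint, after a refractory inter-saccadic interval
  isi <- pmax(stats::rnorm(n_trials, 150, 30), 80)
  corr_target <- correct_dir * ecc + stats::rnorm(n_trials, 0, 0.5)
  corr_amp <- corr_target - endpoint
  corr_ms <- main_sequence(pmax(abs(corr_amp), 0.5), kinematics)
  corr_move_start <- move_start + dur + isi
  corr_sc <- mj_crossing_frac(corr_ms$peak_velocity)
  corr_fits <- corr_move_start + corr_ms$duration <
    paradigm$stimulus_duration
  corrected <- draws$wants_corr & corr_fits
  corr_onset <- ifelse(corrected, corr_move_start + corr_sc * corr_ms$duration,
                       NA_real_)
  corr_offset <- ifelse(corrected,
                        corr_move_start + (1 - corr_sc) * corr_ms$duration,
                        NA_real_)

  truth <- data.table::data.table(
    trial_id = seq_len(n_trials),
    condition = design$condition,
    side = design$side,
    outcome = outcome,
    epoch = epoch,
    srt = draws$srt,
    first_direction = first_dir,
    onset_ms = events$stimulus_on + onset,
    offset_ms = events$stimulus_on + offset,
    amplitude = ifelse(has_sacc, amp, NA_real_),
    peak_velocity = ifelse(has_sacc, vpeak, NA_real_),
    duration = ifelse(has_sacc, dur, NA_real_),
    corrected = corrected,
    corrective_onset_ms = events$stimulus_on + corr_onset,
    corrective_offset_ms = events$stimulus_on + corr_offset,
    corrective_amplitude = ifelse(corrected, corr_amp, NA_real_)
  )
  truth$onset_ms[!has_sacc] <- NA_real_
  truth$offset_ms[!has_sacc] <- NA_real_

  gaze <- NULL
  if (trace) {
    t_local <- (seq_len(n_per_trial) - 1) * dt
    x <- numeric(n_trials * n_per_trial)
    valid <- rep(TRUE, n_trials * n_per_trial)
    pos <- 0
    blink <- stats::runif(n_trials) < min(kinematics$blink_rate, 1)
    blink_t0 <- stats::runif(n_trials, 400, 850)
    blink_len <- stats::runif(n_trials, 100, 200)
    ret_t0 <- stats::runif(n_trials, 150, 300)

    add_sacc <- function(xt, t0, dur, from, to) {
      i <- t_local >= t0 & t_local <= t0 + dur
      xt[i] <- from + (to - from) * mj_shape((t_local[i] - t0) / dur)
      xt[t_local > t0 + dur] <- to
      xt
    }

    for (k in seq_len(n_trials)) {
      xt <- rep(pos, n_per_trial)
      if (abs(pos) > 1e-6) {     # refixation during the fixation period
        rms <- main_sequence(max(abs(pos), 0.5), kinematics)
        xt <- add_sacc(xt, ret_t0[k], rms$duration, pos, 0)
        pos <- 0
      }
      if (has_sacc[k]) {
        t0 <- stim_local + move_start[k]
        xt <- add_sacc(xt, t0, dur[k], 0, endpoint[k])
        pos <- endpoint[k]
        if (corrected[k]) {
          ct0 <- stim_local + corr_move_start[k]
          xt <- add_sacc(xt, ct0, corr_ms$duration[k], endpoint[k],
                         corr_target[k])
          pos <- corr_target[k]
        }
      }
      # slow drift, independent per trial, below the amplitude filter
      if (kinematics$drift_sd > 0) {
        xt <- xt + cumsum(stats::rnorm(n_per_trial, 0,
                                       kinematics$drift_sd /
                                         sqrt(n_per_trial)))
      }
      idx <- (k - 1) * n_per_trial + seq_len(n_per_trial)
      x[idx] <- xt
      if (blink[k]) {
        bi <- t_local >= blink_t0[k] & t_local <= blink_t0[k] + blink_len[k]
        valid[idx[bi]] <- FALSE
      }
    }
    n_all <- n_trials * n_per_trial
    x <- x + stats::rnorm(n_all, 0, kinematics$position_noise_sd)
    y <- stats::rnorm(n_all, 0, kinematics$position_noise_sd)
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    gaze <- data.table::data.table(
      time_ms = (seq_len(n_all) - 1) * dt, x = x, y = y, valid = valid)
  }

  structure(list(gaze = gaze, events = events, truth = truth,
                 paradigm = paradigm),
            class = "session")
}

#' Generate a synthetic two-group cohort
#'
#' Simulates one session per subject for each group, with per-subject
#' behavioral profiles jittered around the group profile: latency means by a
#' normal deviate (`latency_jitter_sd` ms) and probabilities on the logit
#' scale (`logit_jitter_sd`). Subject metadata includes group, age, and — for
#' the patient-like group — a CAG repeat length drawn from 40..52 (the
#' clinically typical adult-onset expansion range), from which the
#' disease-burden score can be computed downstream.
#'
#' All per-subject randomness derives from `seed` through one draw of
#' sub-seeds, so a cohort is reproducible as a whole and per subject.
#'
#' @param n_subjects_per_group Subjects per group (scalar, or vector named
#'   after groups).
#' @param group_profiles Named list of [behavior_profile()]s, one per group.
#'   Default: a `control` and a `patient` group with preset profiles.
#' @param paradigm,kinematics Shared session configuration.
#' @param seed Master integer seed.
#' @param latency_jitter_sd Between-subject SD of latency means, ms.
#' @param logit_jitter_sd Between-subject SD of logit-probabilities.
#' @param trace Passed to [generate_session()].
#' @return A list of class `cohort` with `sessions` (named list of `session`
#'   objects), `metadata` (data.table: `subject_id`, `group`, `age`, `cag`,
#'   `seed`), and the resolved configuration.
#' @export
generate_cohort <- function(n_subjects_per_group = 23,
                            group_profiles = list(control = control_profile(),
                                                  patient = patient_profile()),
                            paradigm = paradigm_config(),
                            kinematics = kinematic_model(),
                            seed = 1L,
                            latency_jitter_sd = 15,
                            logit_jitter_sd = 0.25,
                            trace = TRUE) {
  stopifnot(length(group_profiles) >= 1, !is.null(names(group_profiles)),
            all(n_subjects_per_group >= 1))
  groups <- names(group_profiles)
  n_per <- if (length(n_subjects_per_group) == 1) {
    stats::setNames(rep(n_subjects_per_group, length(groups)), groups)
  } else n_subjects_per_group[groups]

  with_seed_(seed, {
    n_total <- sum(n_per)
    sub_seeds <- sample.int(.Machine$integer.max, n_total)
    group_vec <- rep(groups, n_per)
    ids <- sprintf("S%03d", seq_len(n_total))
    age <- round(rtruncnorm_(n_total, 49.7, 11, 29, 68), 1)
    cag <- rep(NA_integer_, n_total)
    pat <- group_vec == "patient"
    cag[pat] <- as.integer(round(rtruncnorm_(sum(pat), 44.2, 3, 40, 52)))

    sessions <- vector("list", n_total)
    names(sessions) <- ids
    for (i in seq_len(n_total)) {
      prof <- jitter_profile_(group_profiles[[group_vec[i]]],
                              latency_jitter_sd, logit_jitter_sd)
      sessions[[i]] <- generate_session(paradigm, prof, kinematics,
                                        seed = sub_seeds[i], trace = trace)
    }
    metadata <- data.table::data.table(
      subject_id = ids, group = group_vec, age = age, cag = cag,
      seed = sub_seeds)
    structure(list(sessions = sessions, metadata = metadata,
                   paradigm = paradigm, kinematics = kinematics,
                   group_profiles = group_profiles),
              class = "cohort")
  })
}

logit_ <- function(p) log(p / (1 - p))
inv_logit_ <- function(x) 1 / (1 + exp(-x))

jitter_profile_ <- function(profile, latency_sd, logit_sd) {
  p <- unclass(profile)
  for (f in c("regular_latency_mean_pro", "regular_latency_mean_anti")) {
    p[[f]] <- p[[f]] + stats::rnorm(1, 0, latency_sd)
  }
  p$express_latency_mean <- p$express_latency_mean + stats::rnorm(1, 0, 3)
  for (f in c("anticipatory_rate_pro", "anticipatory_rate_anti",
              "express_weight_pro", "express_weight_anti",
              "direction_error_prob_express", "direction_error_prob_regular")) {
    q <- min(max(p[[f]], 1e-4), 1 - 1e-4)
    p[[f]] <- inv_logit_(logit_(q) + stats::rnorm(1, 0, logit_sd))
  }
  # renormalize if jitter pushed the mixture past 1
  for (cond in c("pro", "anti")) {
    a <- p[[paste0("anticipatory_rate_", cond)]]
    e <- p[[paste0("express_weight_", cond)]]
    tot <- a + e + p$no_response_prob
    if (tot > 0.99) {
      sc <- 0.99 / tot
      p[[paste0("anticipatory_rate_", cond)]] <- a * sc
      p[[paste0("express_weight_", cond)]] <- e * sc
    }
  }
  do.call(behavior_profile, p)
}

#' Simulate anti-trial SRT samples from a two-component error/correct mixture
#'
#' Draws saccadic reaction times for anti-saccade trials in which direction
#' errors form an early, narrow latency component and correct anti-saccades a
#' later, broader one — the structure that makes the express epoch detectable
#' from the error-versus-correct histogram. Used to exercise the epoch
#' delimitation procedure at known ground truth.
#'
#' @param n Number of trials.
#' @param error_frac Fraction of direction-error trials.
#' @param error_mean,error_sd Error-component latency, ms (truncated at
#'   `error_lower`).
#' @param error_lower Lower truncation of the error component, ms.
#' @param correct_mean,correct_sd Correct-component latency, ms.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `srt` (ms) and `outcome`
#'   (`"direction_error"` / `"correct"`).
#' @export
simulate_anti_srt <- function(n, error_frac = 0.6,
                              error_mean = 115, error_sd = 12,
                              error_lower = 90,
                              correct_mean = 250, correct_sd = 60,
                              seed = NULL) {
  draw <- function() {
    is_err <- stats::runif(n) < error_frac
    srt <- numeric(n)
    srt[is_err] <- rtruncnorm_(sum(is_err), error_mean, error_sd,
                               error_lower, Inf)
    srt[!is_err] <- pmax(stats::rnorm(sum(!is_err), correct_mean, correct_sd),
                         0)
    data.frame(srt = srt,
               outcome = ifelse(is_err, "direction_error", "correct"),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

#' @export
print.session <- function(x, ...) {
  n <- nrow(x$events)
  cat("<session>", n, "trials,",
      sum(x$events$condition == "pro"), "pro /",
      sum(x$events$condition == "anti"), "anti;",
      if (is.null(x$gaze)) "no trace" else
        paste0(nrow(x$gaze), " samples at ", x$paradigm$sample_rate, " Hz"),
      "\n")
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$metadata), "subjects:",
      paste(sprintf("%s=%d", names(table(x$metadata$group)),
                    table(x$metadata$group)), collapse = ", "), "\n")
  invisible(x)
}
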