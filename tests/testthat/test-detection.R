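# Velocity estimation and threshold-crossing saccade detection.

test_that("velocity of a constant-position window is below the noise floor", {
  w <- make_window()
  v <- compute_velocity(w)
  expect_true(all(v[!is.na(v)] < 1e-9))
})

test_that("velocity of a linear ramp equals its analytic slope", {
  n <- 200
  tm <- (seq_len(n) - 1) * 2
  w <- make_window(n = n, x = 10 * tm / 1000)     # 10 deg/s
  v <- compute_velocity(w)
  core <- v[!is.na(v)]
  expect_true(all(abs(core - 10) < 1e-9))
})

test_that("SG derivative kernel matches the signal package's filter", {
  skip_if_not_installed("signal")
  for (width in c(5, 7, 9)) {
    ours <- sg_deriv_kernel <- antisaccade:::sg_deriv_kernel(width)
    ref <- signal::sgolay(p = 2, n = width, m = 1)[(width + 1) / 2, ]
    expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("invalid samples propagate to NA velocity", {
  w <- make_window(n = 100)
  w$valid[40:45] <- FALSE
  w$x[40:45] <- NA
  v <- compute_velocity(w)
  expect_true(all(is.na(v[38:47])))
  expect_error(compute_velocity(make_window(n = 4)), "5 valid samples")
})

test_that("synthetic saccade peak velocity is within 5% of analytic value", {
  s <- generate_session(small_paradigm(trials_per_block = 12),
                        kinematics = noiseless_kinematics(), seed = 21)
  w <- segment_trials(s$gaze, s$events)
  tr <- s$truth[!is.na(s$truth$srt) & abs(s$truth$amplitude) > 5, ]
  expect_gt(nrow(tr), 3)
  for (i in seq_len(nrow(tr))) {
    d <- detect_saccades(w[[tr$trial_id[i]]])
    resp <- d$events[d$events$onset >= 0, ][1, ]
    expect_lt(abs(resp$peak_velocity - tr$peak_velocity[i]) /
                tr$peak_velocity[i], 0.05)
  }
})

test_that("fixation-only windows yield no events", {
  w <- make_window()
  d <- detect_saccades(w)
  expect_equal(nrow(d$events), 0)
  expect_false(d$excluded)
})

test_that("onset of a known saccade is localized within 2 samples", {
  s <- generate_session(small_paradigm(trials_per_block = 20),
                        kinematics = noiseless_kinematics(), seed = 22)
  w <- segment_trials(s$gaze, s$events)
  tr <- s$truth[!is.na(s$truth$srt), ]
  for (i in seq_len(nrow(tr))) {
    d <- detect_saccades(w[[tr$trial_id[i]]])
    resp <- d$events[d$events$onset >= -250, ]
    expect_gte(nrow(resp), 1)
    expect_lte(abs(resp$onset[1] - tr$srt[i]), 4)   # 2 samples at 500 Hz
  }
})

test_that("an error trial with correction yields two opposite saccades", {
  prof <- behavior_profile(anticipatory_rate_pro = 0,
                           anticipatory_rate_anti = 0,
                           express_weight_pro = 0, express_weight_anti = 0,
                           direction_error_prob_regular = 1,
                           correction_prob = 1, no_response_prob = 0)
  s <- generate_session(small_paradigm(trials_per_block = 10), prof,
                        noiseless_kinematics(), seed = 23)
  w <- segment_trials(s$gaze, s$events)
  tr <- s$truth[s$truth$condition == "anti" & s$truth$corrected, ]
  expect_gt(nrow(tr), 2)
  for (i in seq_len(nrow(tr))) {
    d <- detect_saccades(w[[tr$trial_id[i]]])
    resp <- d$events[d$events$onset >= 0, ]
    expect_equal(nrow(resp), 2)
    expect_equal(resp$direction[1], -resp$direction[2])
  }
})

test_that("noiseless run boundaries equal a brute-force crossing scan", {
  s <- generate_session(small_paradigm(trials_per_block = 10),
                        kinematics = noiseless_kinematics(), seed = 24)
  w <- segment_trials(s$gaze, s$events)
  for (i in seq_along(w)) {
    v <- compute_velocity(w[[i]])
    ref <- brute_force_runs(v, w[[i]]$time_ms)
    d <- detect_saccades(w[[i]], merge_gap = 0, min_duration = 0,
                         min_amplitude = 0)
    if (is.null(ref)) {
      expect_equal(nrow(d$events), 0)
    } else {
      expect_equal(d$events$onset, ref$onset)
      expect_equal(d$events$offset, ref$offset)
    }
  }
})

test_that("raising the threshold never increases the event count", {
  s <- generate_session(small_paradigm(trials_per_block = 6), seed = 25)
  w <- segment_trials(s$gaze, s$events)
  for (i in seq_along(w)) {
    counts <- vapply(c(30, 60, 120, 240),
                     function(th) nrow(detect_saccades(w[[i]],
                                                       threshold = th)$events),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("blink-overlapping events are dropped and lossy windows excluded", {
  n <- 500
  tm <- (seq_len(n) - 1) * 2 - 200
  x <- c(rep(0, 200), 10 * antisaccade:::mj_shape(seq(0, 1, length.out = 25)),
         rep(10, n - 225))
  w <- make_window(n = n, x = x)
  w$valid[195:215] <- FALSE   # blink over the movement
  w$x[!w$valid] <- NA
  d <- detect_saccades(w)
  expect_equal(nrow(d$events), 0)
  expect_true(d$flagged)
  w2 <- make_window(n = 100)
  w2$valid[1:40] <- FALSE
  d2 <- detect_saccades(w2)
  expect_true(d2$excluded)
})

test_that("detection recovers ground truth with near-perfect recall/precision", {
  co <- generate_cohort(2, paradigm = paradigm_config(trials_per_block = 60,
                                                      n_blocks = 1),
                        seed = 26)
  hits <- 0; n_truth <- 0; n_det <- 0
  for (id in co$metadata$subject_id) {
    s <- co$sessions[[id]]
    w <- segment_trials(s$gaze, s$events)
    det <- detect_session(w)
    for (k in seq_along(det)) {
      tid <- attr(det[[k]], "trial_id")
      tr <- s$truth[s$truth$trial_id == tid, ]
      stim_on <- s$events$stimulus_on[s$events$trial_id == tid]
      truth_onsets <- c(tr$srt, tr$corrective_onset_ms - stim_on)
      truth_onsets <- truth_onsets[!is.na(truth_onsets)]
      det_onsets <- det[[k]]$events$onset[det[[k]]$events$onset >= 0]
      n_truth <- n_truth + length(truth_onsets)
      n_det <- n_det + length(det_onsets)
      hits <- hits + sum(vapply(truth_onsets, function(t0)
        any(abs(det_onsets - t0) <= 10), logical(1)))
    }
  }
  expect_gte(hits / n_truth, 0.99)   # recall
  expect_gte(hits / n_det, 0.99)     # precision
})
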