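# Synthetic session/cohort generator: structure, determinism, mixture
# fidelity against its own ground truth.

test_that("default paradigm yields 240 trials split evenly by condition", {
  s <- generate_session(seed = 7, trace = FALSE)
  expect_equal(nrow(s$events), 240)
  expect_equal(sum(s$events$condition == "pro"), 120)
  expect_equal(sum(s$events$condition == "anti"), 120)
  expect_equal(sum(s$events$side == "left"), 120)
  # event timing invariants
  expect_true(all(s$events$gap_on - s$events$fixation_on == 1000))
  expect_true(all(s$events$stimulus_on - s$events$gap_on == 200))
  expect_true(all(s$events$stimulus_off - s$events$stimulus_on == 1000))
})

test_that("trace length matches paradigm duration at the sample rate", {
  p <- small_paradigm(trials_per_block = 6)
  s <- generate_session(p, seed = 2)
  expect_equal(nrow(s$gaze), 6 * trial_duration(p) * p$sample_rate / 1000)
  expect_equal(median(diff(s$gaze$time_ms)), 1000 / p$sample_rate)
})

test_that("degenerate all-no-response profile emits a flat trace", {
  prof <- behavior_profile(anticipatory_rate_pro = 0,
                           anticipatory_rate_anti = 0,
                           express_weight_pro = 0, express_weight_anti = 0,
                           no_response_prob = 1)
  s <- generate_session(small_paradigm(), prof, noiseless_kinematics(),
                       seed = 3)
  expect_true(all(s$truth$outcome == "no_response"))
  expect_lt(max(abs(s$gaze$x)), 0.5)  # never leaves fixation noise range
})

test_that("profiles with mixture weights above 1 are rejected", {
  expect_error(behavior_profile(anticipatory_rate_pro = 0.6,
                                express_weight_pro = 0.5),
               "exceed 1")
  expect_error(behavior_profile(express_weight_anti = 1.2), "\\[0, 1\\]")
})

test_that("identical seed gives identical output; different seed differs", {
  p <- small_paradigm()
  a <- generate_session(p, seed = 42)
  b <- generate_session(p, seed = 42)
  expect_identical(a, b)
  c <- generate_session(p, seed = 43)
  expect_false(identical(a$truth$srt, c$truth$srt))
})

test_that("generated anti SRT mean matches the regular component mean", {
  prof <- behavior_profile(anticipatory_rate_pro = 0,
                           anticipatory_rate_anti = 0,
                           express_weight_pro = 0, express_weight_anti = 0,
                           direction_error_prob_express = 0,
                           direction_error_prob_regular = 0,
                           no_response_prob = 0)
  p <- paradigm_config(trials_per_block = 5000, n_blocks = 2)
  s <- generate_session(p, prof, seed = 11, trace = FALSE)
  anti <- s$truth$srt[s$truth$condition == "anti"]
  # the regular component is truncated to (140, 1000]; the generator's own
  # draws define the expected mean of that truncated distribution
  mu <- mean(anti)
  sem <- sd(anti) / sqrt(length(anti))
  tn_mean <- {
    a <- (140 - 270) / 60
    b <- (1000 - 270) / 60
    270 + 60 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  expect_lt(abs(mu - tn_mean), 2 * sem)
})

test_that("epoch proportions match mixture weights within 3 binomial SE", {
  prof <- behavior_profile(anticipatory_rate_anti = 0.15,
                           express_weight_anti = 0.25,
                           no_response_prob = 0)
  p <- paradigm_config(trials_per_block = 3000, n_blocks = 2)
  s <- generate_session(p, prof, seed = 5, trace = FALSE)
  anti <- s$truth[s$truth$condition == "anti", ]
  n <- nrow(anti)
  for (ep in c("anticipatory", "express")) {
    w <- c(anticipatory = 0.15, express = 0.25)[[ep]]
    se <- sqrt(w * (1 - w) / n)
    expect_lt(abs(mean(anti$epoch == ep) - w), 3 * se)
  }
})

test_that("ground-truth saccades exceed the velocity criterion in-trace", {
  s <- generate_session(small_paradigm(trials_per_block = 20), seed = 9)
  w <- segment_trials(s$gaze, s$events)
  tr <- s$truth[!is.na(s$truth$srt), ]
  for (i in seq_len(nrow(tr))) {
    win <- w[[tr$trial_id[i]]]
    v <- compute_velocity(win)
    srt0 <- tr$onset_ms[i] - s$events$stimulus_on[tr$trial_id[i]]
    srt1 <- tr$offset_ms[i] - s$events$stimulus_on[tr$trial_id[i]]
    inside <- win$time_ms >= srt0 & win$time_ms <= srt1
    expect_gt(max(v[inside], na.rm = TRUE), 30)
  }
})

test_that("cohort has the requested structure and CAG range", {
  co <- generate_cohort(n_subjects_per_group = 23,
                        paradigm = small_paradigm(trials_per_block = 2),
                        seed = 1)
  expect_length(co$sessions, 46)
  expect_equal(nrow(co$metadata), 46)
  pat <- co$metadata[co$metadata$group == "patient", ]
  expect_equal(nrow(pat), 23)
  expect_true(all(pat$cag >= 40 & pat$cag <= 52))
  expect_true(all(is.na(co$metadata$cag[co$metadata$group == "control"])))
  # one subject per group also works
  co1 <- generate_cohort(1, paradigm = small_paradigm(trials_per_block = 2),
                         seed = 2, trace = FALSE)
  expect_equal(nrow(co1$metadata), 2)
})

test_that("group profiles with different anti-error rates separate in truth", {
  profs <- list(control = control_profile(direction_error_prob_regular = 0.15),
                patient = patient_profile(direction_error_prob_regular = 0.45))
  co <- generate_cohort(5, group_profiles = profs,
                        paradigm = paradigm_config(trials_per_block = 60,
                                                   n_blocks = 1),
                        seed = 3, trace = FALSE)
  err_rate <- function(grp) {
    tr <- do.call(rbind, lapply(
      co$sessions[co$metadata$subject_id[co$metadata$group == grp]],
      function(s) s$truth))
    anti <- tr[tr$condition == "anti" &
                 tr$outcome %in% c("correct", "direction_error"), ]
    mean(anti$outcome == "direction_error")
  }
  expect_gt(err_rate("patient") - err_rate("control"), 0)
})

test_that("simulated anti SRT mixture has the requested composition", {
  d <- simulate_anti_srt(5000, seed = 4)
  expect_equal(nrow(d), 5000)
  err <- d$srt[d$outcome == "direction_error"]
  expect_true(all(err >= 90))
  se <- sqrt(0.6 * 0.4 / 5000)
  expect_lt(abs(mean(d$outcome == "direction_error") - 0.6), 3 * se)
  expect_lt(abs(mean(d$srt[d$outcome == "correct"]) - 250), 4)
  expect_identical(simulate_anti_srt(100, seed = 8),
                   simulate_anti_srt(100, seed = 8))
})
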