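# Shared fixtures: small paradigms and canned windows built in code.

small_paradigm <- function(trials_per_block = 10, n_blocks = 1, ...) {
  paradigm_config(trials_per_block = trials_per_block, n_blocks = n_blocks,
                  ...)
}

noiseless_kinematics <- function(...) {
  kinematic_model(position_noise_sd = 0, blink_rate = 0, drift_sd = 0, ...)
}

# a bare trial window: constant position unless a saccade profile is given
make_window <- function(n = 500, dt = 2, x = rep(0, n), y = rep(0, n),
                        valid = rep(TRUE, n), t0 = -200) {
  data.table::data.table(time_ms = t0 + (seq_len(n) - 1) * dt,
                         x = x, y = y, valid = valid)
}

# brute-force reference for threshold-run extraction (no merging/filtering)
brute_force_runs <- function(v, tm, threshold = 30) {
  above <- !is.na(v) & v > threshold
  out <- NULL
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      out <- rbind(out, data.frame(onset = tm[i], offset = tm[j]))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# one-row saccade event table for scoring tests
evt <- function(onset, direction, amplitude = direction * 10,
                offset = onset + 40) {
  data.frame(onset = onset, offset = offset, latency = onset,
             amplitude = amplitude, peak_velocity = 400,
             direction = direction)
}
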