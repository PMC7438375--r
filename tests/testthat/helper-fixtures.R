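# shared fixtures: all built in code at test time

# a calibration whose math is trivially checkable: newton = raw / 500
linear_curve <- function() {
  fit_calibration(data.frame(raw = c(0, 500, 1000), newton = c(0, 1, 2)))
}

# cue parameters with every noise source off
quiet_cue <- function(...) {
  cue_model_params(report_noise_sd = 0, report_bias = 0, ...)
}

# a deterministic generator setup: no trial noise, no participant spread
quiet_between <- function() {
  list(bias_sd = 0, block_bias_sd = 0, force_mean_sd = 0,
       weight_scale_sd = 0, latency_intercept_sd = 0)
}

quiet_force <- function(...) {
  force_model_params(latency_noise_sd = 0, trace_noise_sd = 0, ...)
}

# hand-rolled trial table for filter tests: reports and forces are set
# directly, traces synthesised to match the wanted peak force
make_trial_table <- function(reported_time, peak_force, participant = "P001",
                             condition = "AO", force_condition = "free",
                             valid = TRUE) {
  n <- length(reported_time)
  peak_force <- rep_len(peak_force, n)
  valid <- rep_len(valid, n)
  curve <- default_calibration()
  onset <- seq(0, by = 4000, length.out = n)
  traces <- lapply(seq_len(n), function(i) {
    if (valid[i]) {
      generate_force_trace(peak_force[i], 56, quiet_force(), curve)
    } else {
      structure(list(samples = rep(0L, 520), t0 = 0, sampling_rate = 518),
                class = "force_trace")
    }
  })
  kp_angle <- ((onset %% 1800) / 5) %% 360
  tibble::tibble(
    participant_id = rep_len(participant, n),
    study_tag = "fixture",
    condition = rep_len(condition, n),
    force_condition = rep_len(force_condition, n),
    keypress_onset = onset,
    keypress_offset = onset + 150,
    reported_angle = (kp_angle + reported_time / 5) %% 360,
    sound_onset = ifelse(rep_len(condition, n) == "AS", onset + 250, NA_real_),
    trace = traces)
}

# literal sequential re-implementation of the cascade, used as the oracle
oracle_filter <- function(rt, pf, valid) {
  k1 <- abs(rt - median(rt)) <= 450
  rt1 <- rt[k1]
  k2 <- k1
  if (sd(rt1) > 0) {
    for (i in which(k1)) if (abs(rt[i] - mean(rt1)) > 3 * sd(rt1)) k2[i] <- FALSE
  }
  k3 <- k2 & valid
  pf3 <- pf[k3]
  k4 <- k3
  if (length(pf3) > 1 && sd(pf3) > 0) {
    for (i in which(k3)) if (abs(pf[i] - mean(pf3)) > 3 * sd(pf3)) k4[i] <- FALSE
  }
  k4
}
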