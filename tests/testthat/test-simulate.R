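test_that("a generated trace round-trips its peak through extraction", {
  curve <- default_calibration()
  tr <- generate_force_trace(1.2, 56, force_model_params(), curve, seed = 1)
  f <- extract_peak_force(tr, curve)
  step <- raw_to_newton(round(newton_to_raw(1.2, curve)) + 1, curve) -
    raw_to_newton(round(newton_to_raw(1.2, curve)) - 1, curve)
  expect_lt(abs(f$peak_force - 1.2), step)
  expect_lt(abs(f$peak_latency - 56), 1000 / 518 + 1e-9)
  expect_true(f$valid_force)
})

test_that("trace generation rejects non-positive and unrepresentable forces", {
  expect_error(generate_force_trace(0, 56), "> 0")
  expect_error(generate_force_trace(-1, 56), "> 0")
  expect_error(generate_force_trace(50, 56), "representable")
  expect_error(generate_force_trace(1, 2000), "trace_duration")
})

test_that("extraction agrees with an exhaustive scan of the emitted samples", {
  curve <- default_calibration()
  tr <- generate_force_trace(3.1, 70, force_model_params(), curve, seed = 7)
  got <- extract_peak_force(tr, curve)
  # oracle: brute-force max over calibrated samples in the window
  t <- tr$t0 + (seq_along(tr$samples) - 1) * 1000 / tr$sampling_rate
  fn <- raw_to_newton(tr$samples, curve)
  in_win <- t >= 0 & t <= 800
  i <- which(in_win)[which.max(fn[in_win])]
  expect_identical(got$peak_force, fn[i])
  expect_identical(got$peak_latency, t[i])
})

test_that("noise-free traces are unimodal and decay toward baseline", {
  curve <- default_calibration()
  tr <- generate_force_trace(2.5, 80, quiet_force(), curve)
  s <- tr$samples
  i <- which.max(s)
  expect_true(all(diff(s[1:i]) >= 0))
  expect_true(all(diff(s[i:length(s)]) <= 0))
  expect_lt(raw_to_newton(s[length(s)], curve), 0.05)
  expect_true(all(s >= 0 & s <= 1023))
})

test_that("AO report equals the somatosensory cue when noise is off", {
  cue <- quiet_cue(s_base = 0, s_latency_gain = 0.5)
  # S = 0.5 * 60 = 30, already on the 10 ms grid
  expect_equal(simulate_reported_time("AO", 1.2, 60, cue), 30)
  # forcing B1 = 1 makes AS identical to AO for the same force
  cue_b1 <- quiet_cue(weight_scale = 0)
  f <- seq(0.3, 3, by = 0.3)
  expect_equal(simulate_reported_time("AS", f, 50, cue_b1),
               simulate_reported_time("AO", f, 50, cue_b1))
})

test_that("the weighted average reproduces hand arithmetic and quantizes to the clock", {
  # B1 = 0.9 for every force (slope 0), S = 40: 0.9*40 + 0.1*250 = 61 -> 60
  cue <- quiet_cue(s_base = 40, s_latency_gain = 0, weight_scale = 0.1,
                   weight_slope = 0)
  expect_equal(simulate_reported_time("AS", 1, 999, cue), 60)
})

test_that("reports are multiples of the clock resolution", {
  cue <- cue_model_params()
  r <- simulate_reported_time(rep(c("AO", "AS"), 50), runif(100, 0.5, 3),
                              runif(100, 30, 90), cue, seed = 4)
  expect_true(all(r %% cue$clock_resolution == 0))
})

test_that("somatosensory weight is in [0,1], non-decreasing, and 1 in AO", {
  cue <- cue_model_params(weight_scale = 0.8, weight_slope = 1.2)
  f <- seq(0.01, 6, length.out = 200)
  w <- somato_weight(f, cue)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) >= 0))
  # AO pathway ignores the weight entirely
  cueq <- quiet_cue(weight_scale = 0.8, weight_slope = 1.2)
  expect_equal(simulate_reported_time("AO", 5, 50, cueq),
               simulate_reported_time("AO", 0.1, 50, cueq))
})

test_that("noise-free reports move with force in opposite directions by condition", {
  cue <- quiet_cue()
  force <- quiet_force()
  f <- seq(0.2, 2.0, by = 0.05)
  lat <- force$latency_intercept + force$latency_gain * f
  ao <- simulate_reported_time("AO", f, lat, cue)
  as_ <- simulate_reported_time("AS", f, lat, cue)
  expect_true(all(diff(ao) >= 0))
  expect_true(all(diff(as_) <= 0))
})

test_that("noise-free binding is smaller under strong than light force", {
  cue <- quiet_cue()
  force <- quiet_force()
  bind_at <- function(f) {
    lat <- force$latency_intercept + force$latency_gain * f
    simulate_reported_time("AS", f, lat, cue) -
      simulate_reported_time("AO", f, lat, cue)
  }
  expect_gt(bind_at(1.18), bind_at(3.10))
})

test_that("generate_dataset is deterministic and well-formed", {
  d1 <- generate_dataset(3, 8, "study1", master_seed = 99)
  d2 <- generate_dataset(3, 8, "study1", master_seed = 99)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 3 * 2 * 8)
  expect_true(all(d1$keypress_offset > d1$keypress_onset))
  expect_true(all(d1$reported_angle >= 0 & d1$reported_angle < 360))
  ao <- d1$condition == "AO"
  expect_true(all(is.na(d1$sound_onset[ao])))
  expect_equal(d1$sound_onset[!ao], d1$keypress_onset[!ao] + 250)
  gt <- ground_truth(d1)
  expect_equal(nrow(gt$participants), 3)
  expect_setequal(names(gt$participants),
                  c("participant_id", "report_bias", "force_mean_shift",
                    "weight_scale", "latency_intercept", "seed"))
})

test_that("a fully quiet single trial reports exactly the somatosensory cue", {
  cue <- quiet_cue()
  force <- quiet_force()
  d <- generate_dataset(1, 1, "study1", cue = cue, force = force,
                        between = quiet_between(), master_seed = 5)
  feats <- compute_trial_features(d)
  gt <- ground_truth(d)
  s <- cue$s_base + cue$s_latency_gain * gt$trials$.true_peak_latency
  expect_equal(feats$reported_time[feats$condition == "AO"],
               round(s[gt$trials$condition == "AO"] / 10) * 10)
})
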