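test_that("clock angles convert at 5 ms per degree with signed wrapping", {
  expect_equal(clock_angle_to_time(92, 90), 10)   # one 2-degree hand step
  expect_equal(clock_angle_to_time(90, 90), 0)
  expect_equal(clock_angle_to_time(0, 90), -450)  # a quarter turn back
  expect_equal(clock_angle_to_time(180, 90), 450)
  # wrap across 0/360: nearest signed offset is chosen
  expect_equal(clock_angle_to_time(350, 10), -100)
  expect_equal(clock_angle_to_time(10, 350), 100)
  expect_error(clock_angle_to_time(360, 0))
})

test_that("flat traces carry no reliable keypress force", {
  flat <- structure(list(samples = rep(0L, 520), t0 = 0, sampling_rate = 518),
                    class = "force_trace")
  f <- extract_peak_force(flat)
  expect_false(f$valid_force)
  expect_error(extract_peak_force(structure(list(samples = integer(0), t0 = 0,
                                                 sampling_rate = 518),
                                            class = "force_trace")),
               "empty")
})

test_that("tied maxima resolve to the earliest sample, matching a full scan", {
  curve <- linear_curve()
  dt <- 1000 / 518
  samples <- rep(0L, 520)
  i40 <- which.min(abs((0:519) * dt - 40))
  i60 <- which.min(abs((0:519) * dt - 60))
  samples[c(i40, i60)] <- 600L
  tr <- structure(list(samples = samples, t0 = 0, sampling_rate = 518),
                  class = "force_trace")
  got <- extract_peak_force(tr, curve)
  # oracle: exhaustive first-occurrence scan
  t <- (0:519) * dt
  fn <- raw_to_newton(samples, curve)
  expect_identical(got$peak_latency, t[which(fn == max(fn))[1]])
  expect_lt(abs(got$peak_latency - 40), dt)
})

test_that("truncated traces are scanned over the available portion and flagged", {
  curve <- linear_curve()
  tr <- structure(list(samples = c(10L, 300L, 50L), t0 = 0, sampling_rate = 518),
                  class = "force_trace")
  f <- extract_peak_force(tr, curve)
  expect_true(f$trace_truncated)
  expect_equal(f$peak_force, 300 / 500)
})

test_that("rule 1 removes reports far from the condition median", {
  tab <- make_trial_table(c(rep(0, 9), 500), 1.5)
  feats <- compute_trial_features(tab)
  res <- reject_trials(feats)
  expect_equal(nrow(res$trials), 9)
  expect_equal(res$report$n_rule1, 1)
  expect_equal(res$report$n_rule2, 0)
  expect_true(all(res$trials$reported_time == 0))
})

test_that("identical trials survive the cascade untouched (zero-SD guard)", {
  tab <- make_trial_table(rep(50, 12), 1.5)
  feats <- compute_trial_features(tab)
  res <- reject_trials(feats)
  expect_equal(nrow(res$trials), 12)
  expect_equal(unlist(res$report[, c("n_rule1", "n_rule2", "n_rule3", "n_rule4")]),
               c(n_rule1 = 0, n_rule2 = 0, n_rule3 = 0, n_rule4 = 0))
})

test_that("a planted 60-trial set removes exactly the planted violators", {
  set.seed(42)
  rt <- round(rnorm(60, 40, 60) / 10) * 10
  pf <- rnorm(60, 1.5, 0.2)
  valid <- rep(TRUE, 60)
  rt[7] <- median(rt) + 500       # rule 1
  rt[13] <- median(rt[-7]) + 420  # inside rule 1, outside 3 SD of survivors
  pf[21] <- 3.6                   # rule 4
  valid[33] <- FALSE              # rule 3
  tab <- make_trial_table(rt, pf, valid = valid)
  feats <- compute_trial_features(tab)
  res <- reject_trials(feats)

  keep <- oracle_filter(feats$reported_time, feats$peak_force, feats$valid_force)
  expect_false(any(keep[c(7, 13, 21, 33)]))
  expect_equal(sort(res$trials$keypress_onset),
               sort(feats$keypress_onset[keep]))
  expect_equal(res$report$n_retained, sum(keep))
  # each planted violator is attributed to its own rule
  expect_gte(res$report$n_rule1, 1)
  expect_gte(res$report$n_rule2, 1)
  expect_equal(res$report$n_rule3, 1)
  expect_gte(res$report$n_rule4, 1)
})

test_that("filter counts always reconcile with the input", {
  d <- generate_dataset(4, 30, "study1", master_seed = 17)
  feats <- compute_trial_features(d)
  res <- reject_trials(feats)
  with(res$report, expect_equal(
    n_rule1 + n_rule2 + n_rule3 + n_rule4 + n_retained, n_input))
  expect_equal(sum(res$report$n_retained), nrow(res$trials))
})

test_that("rule 1 is idempotent on its own output", {
  set.seed(3)
  tab <- make_trial_table(round(rnorm(60, 0, 120) / 10) * 10, 1.5)
  feats <- compute_trial_features(tab)
  once <- reject_trials(feats)
  again <- reject_trials(once$trials)
  expect_equal(again$report$n_rule1, 0)
})

test_that("participants are excluded by trial count and by pre-keypress reports", {
  # P001: only 29 trials survive; P002: mean report -120 ms; P003 clean
  tabs <- dplyr::bind_rows(
    make_trial_table(rep(0, 29), 1.5, participant = "P001"),
    make_trial_table(rep(-120, 40), 1.5, participant = "P002"),
    make_trial_table(rep(30, 40), 1.5, participant = "P003"))
  feats <- compute_trial_features(tabs)
  res <- exclude_participants(reject_trials(feats))
  expect_setequal(unique(res$trials$participant_id), "P003")
  ex <- res$exclusions
  expect_equal(ex$reason[ex$participant_id == "P001"], "min-trials")
  expect_equal(ex$reason[ex$participant_id == "P002"], "pre-keypress report")
})

test_that("the exclusion boundary is strict: 30 trials and exactly -100 ms survive", {
  tabs <- dplyr::bind_rows(
    make_trial_table(rep(-100, 30), 1.5, participant = "P001"),
    make_trial_table(rep(-110, 30), 1.5, participant = "P002"))
  feats <- compute_trial_features(tabs)
  res <- exclude_participants(reject_trials(feats))
  expect_true("P001" %in% res$trials$participant_id)
  expect_false("P002" %in% res$trials$participant_id)
})

test_that("a synthetic cohort with planted violators matches hand enumeration", {
  set.seed(9)
  mk <- function(id, rt_mean, n_keep) {
    rt <- round(rnorm(60, rt_mean, 50) / 10) * 10
    n_bad <- 60 - n_keep
    # rule-1 fodder, split across both sides so the median stays put
    if (n_bad > 0) rt[seq_len(n_bad)] <- rt_mean + 600 * rep_len(c(1, -1), n_bad)
    dplyr::bind_rows(
      make_trial_table(rt, rnorm(60, 1.5, 0.15), participant = id,
                       condition = "AO"),
      make_trial_table(round(rnorm(60, rt_mean + 25, 50) / 10) * 10,
                       rnorm(60, 1.4, 0.15), participant = id,
                       condition = "AS"))
  }
  tabs <- dplyr::bind_rows(mk("P001", 40, 60), mk("P002", 40, 25),
                           mk("P003", -150, 60), mk("P004", 35, 60))
  res <- exclude_participants(reject_trials(compute_trial_features(tabs)))
  # hand-derived survivor set: P002 loses 35 AO trials (min-trials),
  # P003 reports ~150 ms before the keypress (pre-keypress rule)
  expect_setequal(unique(res$trials$participant_id), c("P001", "P004"))
  expect_setequal(res$exclusions$participant_id, c("P002", "P003"))
})

test_that("empty condition groups are flagged rather than dropped", {
  tab <- make_trial_table(rep(0, 5), 1.5)
  feats <- compute_trial_features(tab)
  expect_error(reject_trials(feats[0, ]), "empty|missing|group",
               ignore.case = TRUE)
})
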