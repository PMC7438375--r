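test_that("binding t is zero for identical condition samples and positive for a shift", {
  x <- c(-20, 0, 10, 40, 70)
  expect_equal(binding_per_participant(x, x)$t_value, 0)
  res <- binding_per_participant(x + 30, x)
  expect_gt(res$t_value, 0)
  expect_equal(res$raw_diff, 30)
  expect_error(binding_per_participant(1, c(1, 2)), "at least 2")
})

test_that("binding t matches the pooled-variance closed form", {
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(40, 50, 70); b <- rnorm(35, 25, 60)
    res <- binding_per_participant(a, b)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(res$t_value, t_oracle, tolerance = 1e-12)
    expect_equal(res$df, length(a) + length(b) - 2)
    expect_equal(sign(res$t_value), sign(res$raw_diff))
  }
})

test_that("the group binding test is one-tailed with dz = t / sqrt(n)", {
  set.seed(15)
  ao <- rnorm(20, 25, 50)
  as_ <- ao + rnorm(20, 25, 40)
  res <- group_binding_test(as_, ao)
  d <- as_ - ao
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-12)
  expect_equal(res$dz, res$t / sqrt(20), tolerance = 1e-12)
  expect_equal(res$df, 19)
  # one-tailed p is half the two-tailed p when the effect is positive
  expect_equal(res$p, t.test(as_, ao, paired = TRUE)$p.value / 2,
               tolerance = 1e-12)
  # no shift at all: the statistic is defined as zero evidence
  none <- group_binding_test(ao, ao)
  expect_equal(none$t, 0)
  expect_equal(none$p, 0.5)
})

test_that("every 2x2 within-subject F equals the squared paired t of its contrast", {
  set.seed(25)
  n <- 16
  cells <- tidyr::expand_grid(participant_id = sprintf("S%02d", 1:n),
                              condition = c("AO", "AS"),
                              force_condition = c("light", "strong"))
  cells$y <- rnorm(nrow(cells), 50, 30)
  res <- rm_anova_2x2(cells, "y", "participant_id", "condition",
                      "force_condition")
  wide <- tidyr::pivot_wider(cells, names_from = c("condition", "force_condition"),
                             values_from = "y")
  contr <- list(
    condition = (wide$AO_light + wide$AO_strong - wide$AS_light - wide$AS_strong) / 2,
    force_condition = (wide$AO_light + wide$AS_light - wide$AO_strong - wide$AS_strong) / 2,
    `condition:force_condition` = wide$AO_light - wide$AS_light -
      wide$AO_strong + wide$AS_strong)
  for (eff in names(contr)) {
    t_c <- t.test(contr[[eff]])$statistic
    expect_equal(res$F[res$effect == eff], unname(t_c^2), tolerance = 1e-10)
    expect_equal(res$p[res$effect == eff],
                 t.test(contr[[eff]])$p.value, tolerance = 1e-10)
  }
  expect_true(all(res$df1 == 1))
  expect_true(all(res$df2 == n - 1))
  expect_true(all(res$pes >= 0 & res$pes <= 1))
})

test_that("flat cell values give zero F throughout, and missing cells error", {
  cells <- tidyr::expand_grid(participant_id = sprintf("S%02d", 1:6),
                              condition = c("AO", "AS"),
                              force_condition = c("light", "strong"))
  cells$y <- 7
  res <- rm_anova_2x2(cells, "y", "participant_id", "condition",
                      "force_condition")
  expect_equal(res$F, c(0, 0, 0))
  expect_equal(res$pes, c(0, 0, 0))
  expect_error(rm_anova_2x2(cells[-1, ], "y", "participant_id", "condition",
                            "force_condition"), "cell")
})

test_that("precision analysis returns per-cell SDs and recovers a force effect on SD", {
  # noise-free cells: constant reports give SD exactly 0
  tab0 <- make_trial_table(rep(50, 10), 1.5)
  f0 <- compute_trial_features(tab0)
  expect_equal(precision_analysis(f0, anova = FALSE)$cell_sd$sd_report, 0)

  # generator with lower report noise under strong force: ANOVA main effect
  d <- generate_dataset(16, 40, "study2",
                        cue = cue_model_params(report_noise_sd =
                          c(free = 80, light = 90, strong = 45)),
                        master_seed = 33)
  pp <- preprocess(d)
  pr <- precision_analysis(pp$trials)
  light <- pr$cell_sd$sd_report[pr$cell_sd$force_condition == "light"]
  strong <- pr$cell_sd$sd_report[pr$cell_sd$force_condition == "strong"]
  expect_gt(mean(light), mean(strong))
  eff <- pr$anova[pr$anova$effect == "force_condition", ]
  expect_lt(eff$p, 0.05)
})

test_that("binding-vs-integration correlation inherits skipped-Pearson behaviour", {
  expect_error(binding_vs_integration_corr(rep(1, 12), rnorm(12), n_boot = 0),
               "zero variance")
  set.seed(35)
  bt <- rnorm(20); ar <- -0.5 * bt + rnorm(20, sd = 0.4)
  res <- binding_vs_integration_corr(bt, ar, n_boot = 0)
  if (length(res$outlier_indices) == 0) {
    expect_equal(res$r, cor(ar, bt), tolerance = 1e-12)
  }
  expect_lt(res$r, 0)
  expect_lt(res$p_onetailed_neg, 0.05)
})

test_that("participants with stronger auditory integration show larger binding", {
  # heterogeneous weight_scale across participants drives both the binding
  # size and the (negative) AS force-report correlation
  d <- generate_dataset(30, 60, "study1",
                        between = list(bias_sd = 30, block_bias_sd = 10,
                                       force_mean_sd = 0.3,
                                       weight_scale_sd = 0.3,
                                       latency_intercept_sd = 8),
                        master_seed = 71)
  pp <- preprocess(d)
  a <- analyze_study1(pp$trials, n_boot = 0)
  expect_lt(a$binding_vs_as_r$r, 0)
})
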