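#' Per-participant action-binding size
#'
#' The individual binding size is the pooled-variance two-sample t
#' statistic comparing trial-level reported times between the AS and AO
#' conditions (AS minus AO): the t value normalises the mean shift by
#' the trial-level variability and therefore indexes binding more
#' stably than the raw mean difference.
#'
#' @param as_times,ao_times trial-level reported times (ms), >= 2 each.
#' @return tibble with `t_value`, `df`, `raw_diff` (ms, mean AS - mean AO).
#' @export
binding_per_participant <- function(as_times, ao_times) {
  if (length(as_times) < 2 || length(ao_times) < 2) {
    stop("need at least 2 trials per condition", call. = FALSE)
  }
  ht <- stats::t.test(as_times, ao_times, var.equal = TRUE)
  tibble::tibble(t_value = unname(ht$statistic),
                 df = unname(ht$parameter),
                 raw_diff = mean(as_times) - mean(ao_times))
}

#' Group-level action-binding test
#'
#' One-tailed paired t test of per-participant mean reported times,
#' directional hypothesis AS > AO (the reported action time shifts
#' toward the delayed sound).
#'
#' @param as_means,ao_means per-participant condition means (ms), paired.
#' @return tibble with `mean_as`, `mean_ao`, `mean_diff`, `t`, `df`,
#'   `p` (one-tailed) and `dz`.
#' @export
group_binding_test <- function(as_means, ao_means) {
  stopifnot(length(as_means) == length(ao_means))
  if (length(as_means) < 3) stop("need at least 3 participants", call. = FALSE)
  d <- as_means - ao_means
  if (stats::sd(d) == 0 && all(d == 0)) {
    # no shift anywhere: the test statistic carries no evidence either way
    return(tibble::tibble(mean_as = mean(as_means), mean_ao = mean(ao_means),
                          mean_diff = 0, t = 0, df = length(d) - 1,
                          p = 0.5, dz = NaN))
  }
  ht <- stats::t.test(as_means, ao_means, paired = TRUE,
                      alternative = "greater")
  tibble::tibble(mean_as = mean(as_means), mean_ao = mean(ao_means),
                 mean_diff = mean(d),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 dz = if (stats::sd(d) > 0) mean(d) / stats::sd(d) else NaN)
}

#' Cross-participant correlation of binding size with cue integration
#'
#' Skipped Pearson correlation between the per-participant binding t
#' value and the per-participant force-report correlation in the AS
#' condition. A negative coefficient means stronger engagement of
#' auditory-somatosensory integration goes with larger binding; the
#' one-tailed p for that direction is returned by the underlying
#' [skipped_pearson()].
#'
#' @param binding_t per-participant binding t values.
#' @param as_r per-participant AS force-report correlations (paired).
#' @inheritParams skipped_pearson
#' @return a `skipped_corr` object.
#' @export
binding_vs_integration_corr <- function(binding_t, as_r, n_boot = 1000,
                                        seed = NULL) {
  stopifnot(length(binding_t) == length(as_r))
  skipped_pearson(as_r, binding_t, n_boot = n_boot, seed = seed)
}

#' Two-by-two within-subject ANOVA with partial eta squared
#'
#' Repeated-measures ANOVA for a design with two crossed two-level
#' within-participant factors, one observation per cell. Each effect is
#' tested against its own participant-by-effect error stratum
#' (`aov` with an `Error(participant/(A*B))` term); with two-level
#' factors no sphericity correction is needed, and each F(1, n-1)
#' equals the squared paired t of the corresponding contrast. Partial
#' eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param cells data frame with one row per participant x cell.
#' @param value,participant,factor_a,factor_b column names (strings).
#' @return tibble with one row per effect (`factor_a`, `factor_b`,
#'   interaction): `F`, `df1`, `df2`, `p`, `pes`.
#' @export
rm_anova_2x2 <- function(cells, value, participant, factor_a, factor_b) {
  d <- data.frame(y = cells[[value]],
                  id = factor(cells[[participant]]),
                  A = factor(cells[[factor_a]]),
                  B = factor(cells[[factor_b]]))
  if (anyNA(d)) stop("missing cells", call. = FALSE)
  if (nlevels(d$A) != 2 || nlevels(d$B) != 2) {
    stop("both factors must have exactly 2 levels", call. = FALSE)
  }
  counts <- table(d$id, d$A, d$B)
  if (any(counts != 1)) {
    stop("each participant needs exactly one value per cell", call. = FALSE)
  }
  fit <- stats::aov(y ~ A * B + Error(id / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    ss_eff <- tab[rn == effect, "Sum Sq"]
    ss_err <- tab[rn == "Residuals", "Sum Sq"]
    fval <- tab[rn == effect, "F value"]
    pval <- tab[rn == effect, "Pr(>F)"]
    if (ss_eff <= .Machine$double.eps) {
      # a null effect is F = 0 even when the error stratum is empty too
      fval <- 0; pval <- 1
    }
    tibble::tibble(effect = effect,
                   F = fval,
                   df1 = tab[rn == effect, "Df"],
                   df2 = tab[rn == "Residuals", "Df"],
                   p = pval,
                   pes = if (ss_eff <= .Machine$double.eps) 0
                         else ss_eff / (ss_eff + ss_err))
  }
  out <- dplyr::bind_rows(pull("Error: id:A", "A"),
                          pull("Error: id:B", "B"),
                          pull("Error: id:A:B", "A:B"))
  out$effect <- c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":"))
  out
}

#' Report-precision analysis
#'
#' Computes the SD of the reported keypress time per participant and
#' condition cell (a precision index: lower SD = more precise timing)
#' and, for a 2x2 design, runs the within-subject ANOVA on those SDs.
#'
#' @param trials analysis-ready trial table with `reported_time`.
#' @param anova run the 2x2 ANOVA on the SDs (requires two force
#'   conditions; default TRUE when present).
#' @return list with `cell_sd` (tibble: participant, condition, force
#'   condition, `sd_report`, `n`) and `anova` (or NULL).
#' @export
precision_analysis <- function(trials, anova = NULL) {
  cell_sd <- trials |>
    dplyr::group_by(.data$participant_id, .data$condition,
                    .data$force_condition) |>
    dplyr::summarise(sd_report = stats::sd(.data$reported_time),
                     n = dplyr::n(), .groups = "drop")
  if (any(cell_sd$n < 2)) {
    stop("cells with fewer than 2 trials: SD undefined", call. = FALSE)
  }
  two_by_two <- length(unique(cell_sd$condition)) == 2 &&
    length(unique(cell_sd$force_condition)) == 2
  if (is.null(anova)) anova <- two_by_two
  fit <- NULL
  if (anova) {
    if (!two_by_two) stop("ANOVA requires a 2x2 design", call. = FALSE)
    fit <- rm_anova_2x2(cell_sd, "sd_report", "participant_id",
                        "condition", "force_condition")
  }
  list(cell_sd = cell_sd, anova = fit)
}

#' Study-1 analysis: free-press binding and force-report coupling
#'
#' Runs the full single-study analysis on a preprocessed free-press
#' trial table: per-participant skipped correlations between peak force
#' and reported time (per condition), their group-level tests and
#' normality checks, the force/peak-latency correlation, per-participant
#' binding t values, the group binding test, and the cross-participant
#' correlation between binding size and the AS force-report coupling.
#'
#' @param trials analysis-ready trial table (AO and AS, free pressing).
#' @param n_boot bootstrap resamples for the cross-participant CI.
#' @param seed integer seed for the bootstrap.
#' @param min_n minimum trials for a per-participant correlation.
#' @return list with `per_participant` (tibble of r values and binding),
#'   `corr_tests`, `normality`, `corr_diff_test`, `binding`,
#'   `binding_vs_as_r` and `force_latency_tests`.
#' @export
analyze_study1 <- function(trials, n_boot = 1000, seed = 1L, min_n = 10) {
  per <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      ao <- df[df$condition == "AO", ]
      as_ <- df[df$condition == "AS", ]
      b <- binding_per_participant(as_$reported_time, ao$reported_time)
      tibble::tibble(
        r_ao = skipped_pearson(ao$peak_force, ao$reported_time,
                               min_n = min_n, n_boot = 0)$r,
        r_as = skipped_pearson(as_$peak_force, as_$reported_time,
                               min_n = min_n, n_boot = 0)$r,
        r_flat_ao = skipped_pearson(ao$peak_force, ao$peak_latency,
                                    min_n = min_n, n_boot = 0)$r,
        r_flat_as = skipped_pearson(as_$peak_force, as_$peak_latency,
                                    min_n = min_n, n_boot = 0)$r,
        mean_ao = mean(ao$reported_time), mean_as = mean(as_$reported_time),
        binding_t = b$t_value, binding_diff = b$raw_diff)
    }) |>
    dplyr::ungroup()

  corr_tests <- dplyr::bind_rows(
    AO = group_corr_test(per$r_ao),
    AS = group_corr_test(per$r_as), .id = "condition")
  corr_diff <- stats::t.test(per$r_as, per$r_ao, paired = TRUE)
  flat_tests <- dplyr::bind_rows(
    AO = group_corr_test(per$r_flat_ao),
    AS = group_corr_test(per$r_flat_as), .id = "condition")
  normality <- dplyr::bind_rows(
    AO = dplyr::bind_cols(test = c("lilliefors", "jarque_bera"),
                          dplyr::bind_rows(lilliefors_test(per$r_ao),
                                           jarque_bera_test(per$r_ao))),
    AS = dplyr::bind_cols(test = c("lilliefors", "jarque_bera"),
                          dplyr::bind_rows(lilliefors_test(per$r_as),
                                           jarque_bera_test(per$r_as))),
    .id = "condition")

  list(per_participant = per,
       corr_tests = corr_tests,
       corr_diff_test = tibble::tibble(t = unname(corr_diff$statistic),
                                       df = unname(corr_diff$parameter),
                                       p = corr_diff$p.value),
       force_latency_tests = flat_tests,
       normality = normality,
       binding = group_binding_test(per$mean_as, per$mean_ao),
       binding_vs_as_r = binding_vs_integration_corr(
         per$binding_t, per$r_as, n_boot = n_boot, seed = seed))
}

#' Study-2 analysis: binding under controlled light vs strong force
#'
#' For a 2 (AO/AS) x 2 (light/strong) design: per-cell mean reported
#' times, the within-subject ANOVA on reports and on peak forces, the
#' per-force-level binding tests, and the precision (report SD) ANOVA.
#'
#' @param trials analysis-ready trial table from the 2x2 design.
#' @return list with `cell_means`, `anova_report`, `anova_force`,
#'   `binding_by_force` and `precision`.
#' @export
analyze_study2 <- function(trials) {
  cell <- trials |>
    dplyr::group_by(.data$participant_id, .data$condition,
                    .data$force_condition) |>
    dplyr::summarise(mean_report = mean(.data$reported_time),
                     mean_force = mean(.data$peak_force), .groups = "drop")
  wide <- cell |>
    dplyr::select(-"mean_force") |>
    tidyr::pivot_wider(names_from = c("condition", "force_condition"),
                       values_from = "mean_report")
  binding_by_force <- dplyr::bind_rows(
    light = group_binding_test(wide$AS_light, wide$AO_light),
    strong = group_binding_test(wide$AS_strong, wide$AO_strong),
    .id = "force_condition")
  list(cell_means = cell,
       anova_report = rm_anova_2x2(cell, "mean_report", "participant_id",
                                   "condition", "force_condition"),
       anova_force = rm_anova_2x2(cell, "mean_force", "participant_id",
                                  "condition", "force_condition"),
       binding_by_force = binding_by_force,
       precision = precision_analysis(trials))
}
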