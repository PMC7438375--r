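#' Reported-time change per 2 N of peak force
#'
#' Ordinary least-squares regression of trial-level reported time on
#' peak force within one condition of one participant; the slope scaled
#' to a 2 N force increase expresses, in ms, how much the report moves
#' for a fixed, interpretable force change.
#'
#' @param peak_force,reported_time trial-level vectors (>= 3 trials).
#' @return slope * 2, in ms per 2 N.
#' @export
slope_change_2n <- function(peak_force, reported_time) {
  stopifnot(length(peak_force) == length(reported_time))
  if (length(peak_force) < 3) stop("need at least 3 trials", call. = FALSE)
  if (stats::sd(peak_force) == 0) {
    stop("degenerate regression: constant peak force", call. = FALSE)
  }
  2 * unname(stats::coef(stats::lm(reported_time ~ peak_force))[2])
}

#' Participant-resampling bootstrap power curve
#'
#' Estimates, for each candidate sample size, the probability of
#' detecting an effect by repeatedly drawing subsets of participants
#' without replacement from the available cohort and running the
#' detection test on each subset. Note that without-replacement
#' resampling is bounded by the cohort actually tested: at the full
#' cohort size every draw is identical and the estimate degenerates to
#' 0 or 1, so sizes close to the cohort size are flagged with a warning.
#'
#' @param cohort data frame with one row per participant carrying the
#'   statistic(s) the detector needs.
#' @param sizes integer vector of sample sizes (default 20:42).
#' @param reps resamples per size (default 1000).
#' @param alpha detection threshold on the p-value (default 0.05).
#' @param detector either a function `f(subset) -> p-value`, or one of
#'   `"corr"` (two-tailed one-sample t of column `r` against 0) and
#'   `"interaction"` (two-tailed paired t of column `slope_as` against
#'   `slope_ao`, i.e. the force-binding interaction expressed as the
#'   per-participant difference in 2 N slope change).
#' @param seed master integer seed; each (size, rep) draw uses a derived
#'   stream.
#' @return a `power_curve`: tibble with `size` and `power`, with `reps`,
#'   `alpha`, `detector` and `seed` attached as attributes.
#' @export
power_resample <- function(cohort, sizes = 20:42, reps = 1000, alpha = 0.05,
                           detector = "corr", seed = 1L) {
  n <- nrow(cohort)
  if (any(sizes > n)) stop("sizes exceed cohort size", call. = FALSE)
  stopifnot(reps > 0, alpha > 0, alpha < 1)
  tag <- if (is.function(detector)) "custom" else detector
  detect <- if (is.function(detector)) {
    detector
  } else {
    switch(detector,
      corr = function(d) stats::t.test(d$r, mu = 0)$p.value,
      interaction = function(d) {
        stats::t.test(d$slope_as, d$slope_ao, paired = TRUE)$p.value
      },
      stop('detector must be "corr", "interaction" or a function',
           call. = FALSE))
  }
  if (any(sizes >= n - 1)) {
    warning("sample sizes at or near the cohort size: without-replacement ",
            "resampling has few distinct draws there, so very high power ",
            "estimates should be interpreted with caution", call. = FALSE)
  }
  set.seed(seed)
  stream <- matrix(sample.int(.Machine$integer.max - 1L, length(sizes) * reps),
                   nrow = length(sizes))
  power <- vapply(seq_along(sizes), function(si) {
    hits <- vapply(seq_len(reps), function(rp) {
      set.seed(stream[si, rp])
      idx <- sample.int(n, sizes[si], replace = FALSE)
      detect(cohort[idx, , drop = FALSE]) < alpha
    }, logical(1))
    mean(hits)
  }, numeric(1))
  structure(tibble::tibble(size = as.integer(sizes), power = power),
            reps = reps, alpha = alpha, detector = tag, seed = seed,
            class = c("power_curve", class(tibble::tibble())))
}

#' Smallest sample size reaching a power target
#'
#' @param curve a `power_curve` from [power_resample()].
#' @param target power target (default 0.8).
#' @return the smallest size with estimated power >= target, or `NA`
#'   when the curve never reaches it.
#' @export
min_n_for_power <- function(curve, target = 0.8) {
  stopifnot(inherits(curve, "power_curve"))
  hit <- curve$size[curve$power >= target]
  if (length(hit) == 0) return(NA_integer_)
  min(hit)
}

#' Per-participant detector statistics for the power analysis
#'
#' Builds the cohort table consumed by [power_resample()] from an
#' analysis-ready trial table: per participant, the skipped force-report
#' correlation in the chosen condition (column `r`) and the 2 N slope
#' changes in AO and AS (columns `slope_ao`, `slope_as`).
#'
#' @param trials analysis-ready trial table.
#' @param condition condition for the correlation detector (default "AO").
#' @param min_n minimum trials per correlation.
#' @return tibble with one row per participant.
#' @export
power_cohort_stats <- function(trials, condition = "AO", min_n = 10) {
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      cond <- df[df$condition == condition, ]
      ao <- df[df$condition == "AO", ]
      as_ <- df[df$condition == "AS", ]
      tibble::tibble(
        r = skipped_pearson(cond$peak_force, cond$reported_time,
                            min_n = min_n, n_boot = 0)$r,
        slope_ao = slope_change_2n(ao$peak_force, ao$reported_time),
        slope_as = slope_change_2n(as_$peak_force, as_$reported_time))
    }) |>
    dplyr::ungroup()
}
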