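#' Convert a reported clock angle to a reported time
#'
#' The Libet clock completes a revolution in 1800 ms, so 1 degree equals
#' 5 ms and the 2 degree hand step gives the 10 ms report resolution.
#' The reported time is the signed angular distance from the keypress
#' hand position to the reported hand position, wrapped to the nearest
#' offset in \[-180, 180) degrees, i.e. \[-900, 900) ms.
#'
#' @param reported_angle,keypress_angle angles in degrees, in \[0, 360).
#' @param period_ms clock period (default 1800 ms).
#' @return reported time in ms relative to the keypress.
#' @examples
#' clock_angle_to_time(92, 90)  # one 2-degree step = +10 ms
#' clock_angle_to_time(0, 90)   # -450 ms
#' @export
clock_angle_to_time <- function(reported_angle, keypress_angle,
                                period_ms = 1800) {
  stopifnot(all(reported_angle >= 0 & reported_angle < 360),
            all(keypress_angle >= 0 & keypress_angle < 360))
  d <- (reported_angle - keypress_angle) %% 360
  d <- d - 360 * (d >= 180)
  d * period_ms / 360
}

#' Extract peak force and peak-force latency from a trace
#'
#' Calibrates the raw trace to Newtons and takes the maximum in an
#' 800 ms window starting at the keypress; the latency is the time of
#' that maximum from keypress onset, with ties resolved to the earliest
#' sample. A trace with no calibrated sample at or above `min_force` in
#' the window has no reliable keypress force (`valid_force = FALSE`).
#'
#' @param trace a `force_trace` (its `t0` is relative to keypress onset).
#' @param curve an `fsr_calibration`.
#' @param window_ms search-window length from keypress onset (default 800).
#' @param min_force reliability threshold in N (default 0.1).
#' @return list with `peak_force` (N), `peak_latency` (ms),
#'   `valid_force` (logical) and `trace_truncated` (TRUE when the trace
#'   ends before the window does, in which case the available portion is
#'   scanned).
#' @export
extract_peak_force <- function(trace, curve = default_calibration(),
                               window_ms = 800, min_force = 0.1) {
  if (!inherits(trace, "force_trace")) stop("not a force_trace", call. = FALSE)
  if (length(trace$samples) == 0) stop("empty force trace", call. = FALSE)
  dt <- 1000 / trace$sampling_rate
  t <- trace$t0 + (seq_along(trace$samples) - 1L) * dt
  in_win <- t >= 0 & t <= window_ms
  if (!any(in_win)) stop("trace does not cover the search window", call. = FALSE)
  f <- raw_to_newton(trace$samples[in_win], curve)
  i <- which.max(f) # which.max takes the first maximum: earliest-tie rule
  list(peak_force = f[i],
       peak_latency = t[in_win][i],
       valid_force = f[i] >= min_force,
       trace_truncated = max(t) < window_ms)
}

#' Compute per-trial features for a trial table
#'
#' Adds `reported_time` (ms, from the clock angles), `peak_force` (N),
#' `peak_latency` (ms) and `valid_force` to a trial table.
#'
#' @param trials canonical trial table with a `trace` list-column.
#' @param curve an `fsr_calibration`.
#' @inheritParams extract_peak_force
#' @return the trial table with feature columns appended.
#' @export
compute_trial_features <- function(trials, curve = default_calibration(),
                                   window_ms = 800, min_force = 0.1) {
  .check_trial_schema(trials, need_trace = TRUE)
  kp_angle <- ((trials$keypress_onset %% 1800) / 5) %% 360
  feats <- purrr::map(trials$trace, extract_peak_force, curve = curve,
                      window_ms = window_ms, min_force = min_force)
  trials$reported_time <- clock_angle_to_time(trials$reported_angle, kp_angle)
  trials$peak_force <- purrr::map_dbl(feats, "peak_force")
  trials$peak_latency <- purrr::map_dbl(feats, "peak_latency")
  trials$valid_force <- purrr::map_lgl(feats, "valid_force")
  trials
}

#' Trial-rejection cascade
#'
#' Applies, within each participant x condition (x force condition)
#' group and in this order:
#' 1. reported time more than 450 ms (a quarter turn) from the group
#'    median;
#' 2. among survivors, reported time more than 3 SD from the survivor
#'    mean;
#' 3. no reliable keypress force recorded;
#' 4. among survivors, peak force more than 3 SD from the survivor mean.
#'
#' SDs are sample SDs of the survivors at the stage where each rule is
#' applied; a zero or undefined SD removes nothing. Counts for every
#' rule are recorded per group and always reconcile with the input.
#'
#' @param features trial table with feature columns (see
#'   [compute_trial_features()]).
#' @param median_window rule-1 cutoff in ms (default 450).
#' @param sd_mult rule-2/4 cutoff in SD units (default 3).
#' @return list with `trials` (retained rows) and `report` (a tibble:
#'   one row per group with `n_input`, `n_rule1` .. `n_rule4`,
#'   `n_retained`).
#' @export
reject_trials <- function(features, median_window = 450, sd_mult = 3) {
  need <- c("reported_time", "peak_force", "valid_force")
  if (!all(need %in% names(features))) {
    stop("run compute_trial_features() first (missing: ",
         paste(setdiff(need, names(features)), collapse = ", "), ")",
         call. = FALSE)
  }
  if (nrow(features) == 0) stop("empty condition group", call. = FALSE)
  grouped <- dplyr::group_by(features, .data$participant_id,
                             .data$condition, .data$force_condition)
  filt <- function(df, ...) {
    keep1 <- abs(df$reported_time - stats::median(df$reported_time)) <= median_window
    s1 <- df$reported_time[keep1]
    sd1 <- stats::sd(s1)
    keep2 <- keep1
    if (isTRUE(sd1 > 0)) {
      keep2[keep1] <- abs(s1 - mean(s1)) <= sd_mult * sd1
    }
    keep3 <- keep2 & df$valid_force
    pf <- df$peak_force[keep3]
    sd4 <- stats::sd(pf)
    keep4 <- keep3
    if (isTRUE(sd4 > 0)) {
      keep4[keep3] <- abs(pf - mean(pf)) <= sd_mult * sd4
    }
    df$.keep <- keep4
    df$.n_rule1 <- sum(!keep1)
    df$.n_rule2 <- sum(keep1 & !keep2)
    df$.n_rule3 <- sum(keep2 & !keep3)
    df$.n_rule4 <- sum(keep3 & !keep4)
    df
  }
  marked <- dplyr::ungroup(dplyr::group_modify(grouped, filt))
  report <- marked |>
    dplyr::group_by(.data$participant_id, .data$condition,
                    .data$force_condition) |>
    dplyr::summarise(n_input = dplyr::n(),
                     n_rule1 = .data$.n_rule1[1], n_rule2 = .data$.n_rule2[1],
                     n_rule3 = .data$.n_rule3[1], n_rule4 = .data$.n_rule4[1],
                     n_retained = sum(.data$.keep), .groups = "drop")
  kept <- dplyr::select(dplyr::filter(marked, .data$.keep),
                        -dplyr::starts_with(".n_rule"), -".keep")
  list(trials = kept, report = report)
}

#' Participant-exclusion rules
#'
#' Excludes a participant when fewer than `min_trials` trials survive
#' rejection in any condition group (`"min-trials"`), or when the mean
#' reported time in any condition group is more than 100 ms before the
#' keypress (`"pre-keypress report"` — such participants plausibly timed
#' the go-cue rather than the keypress).
#'
#' @param filtered the list returned by [reject_trials()].
#' @param min_trials minimum retained trials per condition (default 30,
#'   half of a 60-trial block).
#' @param pre_cutoff exclusion threshold on the condition-mean reported
#'   time in ms (default -100; strict `<`).
#' @return list with `trials` (analysis table), `exclusions` (tibble of
#'   `participant_id`, `reason`) and the pass-through rejection `report`.
#' @export
exclude_participants <- function(filtered, min_trials = 30, pre_cutoff = -100) {
  stopifnot(is.list(filtered), all(c("trials", "report") %in% names(filtered)))
  by_cond <- filtered$trials |>
    dplyr::group_by(.data$participant_id, .data$condition,
                    .data$force_condition) |>
    dplyr::summarise(mean_rt = mean(.data$reported_time), .groups = "drop")
  few <- filtered$report |>
    dplyr::filter(.data$n_retained < min_trials) |>
    dplyr::distinct(.data$participant_id) |>
    dplyr::mutate(reason = "min-trials")
  early <- by_cond |>
    dplyr::filter(.data$mean_rt < pre_cutoff) |>
    dplyr::distinct(.data$participant_id) |>
    dplyr::mutate(reason = "pre-keypress report")
  exclusions <- dplyr::bind_rows(few, early) |>
    dplyr::distinct(.data$participant_id, .keep_all = TRUE)
  trials <- dplyr::filter(filtered$trials,
                          !.data$participant_id %in% exclusions$participant_id)
  list(trials = trials, exclusions = exclusions, report = filtered$report)
}

#' Full preprocessing: features, trial rejection, participant exclusion
#'
#' @param trials canonical trial table.
#' @param curve an `fsr_calibration`.
#' @param ... passed on to [reject_trials()] and [exclude_participants()]
#'   (`median_window`, `sd_mult`, `min_trials`, `pre_cutoff`).
#' @inheritParams compute_trial_features
#' @return list with `trials` (analysis-ready, with feature columns),
#'   `report` (rejection counts) and `exclusions`.
#' @export
preprocess <- function(trials, curve = default_calibration(),
                       window_ms = 800, min_force = 0.1, ...) {
  dots <- list(...)
  feats <- compute_trial_features(trials, curve, window_ms, min_force)
  rej <- do.call(reject_trials, c(list(feats),
                                  dots[names(dots) %in% c("median_window", "sd_mult")]))
  do.call(exclude_participants, c(list(rej),
                                  dots[names(dots) %in% c("min_trials", "pre_cutoff")]))
}
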