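#' Simulate a single keypress force trace
#'
#' Emits a unimodal force pulse sampled at the sensor rate and digitized
#' to integer raw FSR units in \[0, 1023\]. The noise-free pulse follows
#' a gamma-like rise/fall `F(t) = peak * (t/tp)^k * exp(k * (1 - t/tp))`
#' with its mode at the requested peak latency `tp`; the sample nearest
#' `tp` is pinned to the digitized peak value so that peak extraction
#' recovers the requested peak force to within one quantization step and
#' the requested latency to within one sample.
#'
#' @param peak_force peak force in Newtons (> 0 and representable by the
#'   calibration curve).
#' @param peak_latency peak-force latency in ms, inside
#'   `(0, trace_duration)`.
#' @param params a [force_model_params()] object.
#' @param curve an `fsr_calibration` used to digitize the trace.
#' @param seed optional integer seed for the sensor noise.
#' @return an object of class `force_trace`: list with integer `samples`,
#'   `t0` (ms offset of the first sample from keypress onset, 0 here) and
#'   `sampling_rate` (Hz).
#' @examples
#' tr <- generate_force_trace(1.2, 56, seed = 1)
#' extract_peak_force(tr)
#' @export
generate_force_trace <- function(peak_force, peak_latency,
                                 params = force_model_params(),
                                 curve = default_calibration(),
                                 seed = NULL) {
  stopifnot(inherits(params, "force_model_params"))
  if (!is.finite(peak_force) || peak_force <= 0) {
    stop("peak_force must be > 0", call. = FALSE)
  }
  if (peak_latency <= 0 || peak_latency >= params$trace_duration) {
    stop("peak_latency must lie inside (0, trace_duration)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- 1000 / params$sampling_rate
  n <- floor(params$trace_duration / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  k <- params$pulse_shape
  x <- t / peak_latency
  f_newton <- peak_force * x^k * exp(k * (1 - x))
  raw <- newton_to_raw(f_newton, curve)
  if (params$trace_noise_sd > 0) {
    raw <- raw + stats::rnorm(n, 0, params$trace_noise_sd)
  }
  peak_raw <- round(newton_to_raw(peak_force, curve))
  i_peak <- which.min(abs(t - peak_latency))
  raw <- pmin(pmax(round(raw), 0L), peak_raw)
  raw[i_peak] <- peak_raw
  structure(list(samples = as.integer(raw), t0 = 0,
                 sampling_rate = params$sampling_rate),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat("<force_trace>", length(x$samples), "samples @", x$sampling_rate,
      "Hz, t0 =", x$t0, "ms\n")
  invisible(x)
}

#' Simulate reported keypress times under the cue-integration model
#'
#' In AO the report is the somatosensory cue time
#' `S = s_base + s_latency_gain * peak_latency` plus bias and noise; in
#' AS it is the weighted average `B1(F) * S + (1 - B1(F)) * A` with
#' `A = sound_delay`. Reports are quantized to the clock resolution.
#' All arguments are vectorized over trials.
#'
#' @param condition `"AO"` or `"AS"` (recycled).
#' @param peak_force peak force in N.
#' @param peak_latency peak-force latency in ms.
#' @param cue a [cue_model_params()] object.
#' @param force_condition `"free"`, `"light"` or `"strong"`; selects the
#'   report-noise SD (recycled).
#' @param seed optional integer seed.
#' @return reported keypress time in ms relative to keypress onset,
#'   quantized to `cue$clock_resolution`.
#' @examples
#' cue <- cue_model_params(report_noise_sd = 0)
#' simulate_reported_time("AO", 1.2, 56, cue) # somatosensory cue only
#' simulate_reported_time("AS", 1.2, 56, cue) # pulled toward the sound
#' @export
simulate_reported_time <- function(condition, peak_force, peak_latency,
                                   cue = cue_model_params(),
                                   force_condition = "free",
                                   seed = NULL) {
  stopifnot(inherits(cue, "cue_model_params"))
  if (!all(condition %in% c("AO", "AS"))) {
    stop('condition must be "AO" or "AS"', call. = FALSE)
  }
  if (!all(force_condition %in% c("free", "light", "strong"))) {
    stop('force_condition must be "free", "light" or "strong"', call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(condition), length(peak_force), length(peak_latency),
           length(force_condition))
  condition <- rep_len(condition, n)
  peak_force <- rep_len(peak_force, n)
  peak_latency <- rep_len(peak_latency, n)
  force_condition <- rep_len(force_condition, n)

  s <- cue$s_base + cue$s_latency_gain * peak_latency
  b1 <- ifelse(condition == "AO", 1, somato_weight(peak_force, cue))
  report <- b1 * s + (1 - b1) * cue$sound_delay + cue$report_bias
  noise_sd <- cue$report_noise_sd[force_condition]
  report <- report + stats::rnorm(n, 0, noise_sd)
  round(report / cue$clock_resolution) * cue$clock_resolution
}

.condition_grid <- function(design) {
  switch(design,
    study1 = tidyr::expand_grid(condition = c("AO", "AS"),
                                force_condition = "free"),
    study2 = tidyr::expand_grid(condition = c("AO", "AS"),
                                force_condition = c("light", "strong")),
    stop('design must be "study1" or "study2"', call. = FALSE))
}

#' Generate a synthetic action-binding dataset
#'
#' Simulates a full cohort: per-participant parameters (report bias,
#' per-condition block bias, mean free peak force, somatosensory weight
#' scale, latency intercept) are drawn around the population defaults,
#' then trials with digitized force traces, Libet-clock reports and
#' session-clock event times are generated per condition block. The
#' default calibration gives a mean AO report of roughly 25-50 ms after
#' the keypress, a trial-level report SD near 80 ms and a mean free-press
#' binding effect (AS minus AO) around 25 ms.
#'
#' @param n_participants cohort size.
#' @param n_trials trials per condition block (default 60).
#' @param design `"study1"` (AO/AS under free pressing) or `"study2"`
#'   (AO/AS crossed with light/strong force windows).
#' @param cue,force population-level [cue_model_params()] and
#'   [force_model_params()].
#' @param between named list of between-participant SDs:
#'   `bias_sd` (ms, stable report bias), `block_bias_sd` (ms, per
#'   condition-block bias), `force_mean_sd` (N, free-press mean force),
#'   `weight_scale_sd` (heterogeneity of the auditory-integration
#'   strength), `latency_intercept_sd` (ms).
#' @param master_seed integer; all randomness derives from it.
#' @param curve calibration used to digitize traces.
#' @return a tibble with one row per trial (columns `participant_id`,
#'   `study_tag`, `condition`, `force_condition`, `keypress_onset`,
#'   `keypress_offset`, `reported_angle`, `sound_onset`, `trace`), with
#'   the ground-truth generative record attached as attribute
#'   `"ground_truth"` (see [ground_truth()]).
#' @export
generate_dataset <- function(n_participants,
                             n_trials = 60,
                             design = c("study1", "study2"),
                             cue = cue_model_params(),
                             force = force_model_params(),
                             between = list(bias_sd = 45, block_bias_sd = 35,
                                            force_mean_sd = 0.35,
                                            weight_scale_sd = 0.15,
                                            latency_intercept_sd = 8),
                             master_seed = 1L,
                             curve = default_calibration()) {
  design <- match.arg(design)
  stopifnot(n_participants >= 1, n_trials >= 1)
  grid <- .condition_grid(design)

  set.seed(master_seed)
  part_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  participants <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n_participants)),
    report_bias = stats::rnorm(n_participants, cue$report_bias, between$bias_sd),
    force_mean_shift = stats::rnorm(n_participants, 0, between$force_mean_sd),
    weight_scale = .rtruncnorm(n_participants, cue$weight_scale,
                               between$weight_scale_sd, 0.02, 1),
    latency_intercept = stats::rnorm(n_participants, force$latency_intercept,
                                     between$latency_intercept_sd),
    seed = part_seeds)

  fmax <- raw_to_newton(1023, curve)
  trunc_range <- list(free = c(0.2, min(6, fmax)),
                      light = c(1.06, 1.31), strong = c(2.57, 4.01))

  rows <- purrr::map(seq_len(n_participants), function(i) {
    p <- participants[i, ]
    set.seed(p$seed)
    cue_i <- cue
    cue_i$report_bias <- p$report_bias
    cue_i$weight_scale <- p$weight_scale
    purrr::map(seq_len(nrow(grid)), function(g) {
      cond <- grid$condition[g]
      fcond <- grid$force_condition[g]
      block_bias <- stats::rnorm(1, 0, between$block_bias_sd)
      fm <- if (fcond == "free") {
        force$peak_force_mean[[paste0("free_", tolower(cond))]] + p$force_mean_shift
      } else {
        force$peak_force_mean[[fcond]]
      }
      tr <- trunc_range[[fcond]]
      fm <- min(max(fm, tr[1] + 0.05), tr[2] - 0.05)
      pf <- .rtruncnorm(n_trials, fm, force$peak_force_sd[[fcond]], tr[1], tr[2])
      lat <- p$latency_intercept + force$latency_gain * pf +
        stats::rnorm(n_trials, 0, force$latency_noise_sd)
      lat <- pmin(pmax(lat, 10), min(300, force$trace_duration - 10))
      report <- simulate_reported_time(cond, pf, lat, cue_i, fcond) +
        round(block_bias / cue$clock_resolution) * cue$clock_resolution
      # session clock: inter-trial gaps; onsets on the 10 ms frame grid
      onset <- round(cumsum(stats::runif(n_trials, 3000, 5000)) / 10) * 10
      offset <- onset + pmax(30, stats::rnorm(n_trials, force$press_duration_mean,
                                              force$press_duration_sd))
      kp_angle <- ((onset %% 1800) / 5) %% 360
      reported_angle <- (kp_angle + report / 5) %% 360
      traces <- purrr::map(seq_len(n_trials), function(j) {
        generate_force_trace(pf[j], lat[j], force, curve)
      })
      tibble::tibble(
        participant_id = p$participant_id,
        study_tag = design,
        condition = cond, force_condition = fcond,
        keypress_onset = onset, keypress_offset = offset,
        reported_angle = reported_angle,
        sound_onset = if (cond == "AS") onset + cue$sound_delay else NA_real_,
        trace = traces,
        .true_peak_force = pf, .true_peak_latency = lat, .true_report = report)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  truth <- list(design = design, master_seed = master_seed,
                cue = cue, force = force, between = between,
                participants = participants,
                trials = dplyr::select(
                  tibble::as_tibble(rows),
                  "participant_id", "condition", "force_condition",
                  "keypress_onset", dplyr::starts_with(".true_")))
  out <- dplyr::select(rows, -dplyr::starts_with(".true_"))
  attr(out, "ground_truth") <- truth
  out
}

#' Ground-truth generative record of a synthetic dataset
#'
#' @param trials a trial table produced by [generate_dataset()].
#' @return list with the generative parameters, per-participant sampled
#'   parameters and per-trial latent values.
#' @export
ground_truth <- function(trials) {
  gt <- attr(trials, "ground_truth")
  if (is.null(gt)) stop("no ground-truth record attached", call. = FALSE)
  gt
}
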