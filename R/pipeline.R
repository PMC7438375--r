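#' Pipeline configuration
#'
#' Bundles every tunable of the simulate - preprocess - analyze - power
#' pipeline with the study's standard constants as defaults: 250 ms
#' sound delay, 800 ms peak-force window, the 450 ms / 3 SD rejection
#' rules, the 30-trial and -100 ms participant-exclusion rules, 60
#' trials per condition, power sizes 20-42 with 1000 repetitions.
#'
#' @param design `"study1"` or `"study2"`.
#' @param n_participants cohort size to simulate (42 for study1, 35 for
#'   study2 by default, matching the analysed cohort sizes).
#' @param n_trials trials per condition block.
#' @param cue,force,between generator parameters (see
#'   [generate_dataset()]).
#' @param median_window,sd_mult,min_trials,pre_cutoff preprocessing
#'   thresholds (see [reject_trials()], [exclude_participants()]).
#' @param window_ms,min_force feature-extraction settings.
#' @param power_sizes,power_reps,power_alpha,power_detector power-curve
#'   settings (see [power_resample()]); `power_reps = 0` skips the
#'   power stage.
#' @param n_boot bootstrap resamples for correlation CIs.
#' @param master_seed integer seed driving all randomness.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = c("study1", "study2"),
                            n_participants = NULL,
                            n_trials = 60,
                            cue = cue_model_params(),
                            force = force_model_params(),
                            between = list(bias_sd = 45, block_bias_sd = 35,
                                           force_mean_sd = 0.35,
                                           weight_scale_sd = 0.15,
                                           latency_intercept_sd = 8),
                            median_window = 450, sd_mult = 3,
                            min_trials = 30, pre_cutoff = -100,
                            window_ms = 800, min_force = 0.1,
                            power_sizes = 20:42, power_reps = 1000,
                            power_alpha = 0.05, power_detector = "corr",
                            n_boot = 1000,
                            master_seed = 1L) {
  design <- match.arg(design)
  if (is.null(n_participants)) {
    n_participants <- if (design == "study1") 42L else 35L
  }
  cfg <- list(design = design, n_participants = n_participants,
              n_trials = n_trials, cue = cue, force = force,
              between = between,
              median_window = median_window, sd_mult = sd_mult,
              min_trials = min_trials, pre_cutoff = pre_cutoff,
              window_ms = window_ms, min_force = min_force,
              power_sizes = power_sizes, power_reps = power_reps,
              power_alpha = power_alpha, power_detector = power_detector,
              n_boot = n_boot, master_seed = master_seed)
  .validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.validate_config <- function(cfg) {
  chk <- function(ok, what) {
    if (!isTRUE(ok)) stop("invalid config: ", what, call. = FALSE)
  }
  chk(cfg$n_participants >= 1, "n_participants must be >= 1")
  chk(cfg$n_trials >= 1, "n_trials must be >= 1")
  chk(is.numeric(cfg$median_window) && cfg$median_window > 0,
      "median_window must be a positive number")
  chk(is.numeric(cfg$sd_mult) && cfg$sd_mult > 0,
      "sd_mult must be a positive number")
  chk(cfg$min_trials >= 0, "min_trials must be >= 0")
  chk(is.numeric(cfg$pre_cutoff), "pre_cutoff must be numeric")
  chk(cfg$window_ms > 0, "window_ms must be positive")
  chk(all(cfg$power_sizes >= 2), "power_sizes must be >= 2")
  chk(cfg$power_alpha > 0 && cfg$power_alpha < 1, "power_alpha must be in (0,1)")
  chk(inherits(cfg$cue, "cue_model_params"), "cue must be cue_model_params()")
  chk(inherits(cfg$force, "force_model_params"),
      "force must be force_model_params()")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override [pipeline_config()] defaults;
#' `cue` and `force` sub-maps override individual generator parameters.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("design", "n_participants", "n_trials", "median_window",
               "sd_mult", "min_trials", "pre_cutoff", "window_ms",
               "min_force", "power_reps", "power_alpha", "power_detector",
               "n_boot", "master_seed")
  for (s in intersect(scalars, names(y))) args[[s]] <- y[[s]]
  if (!is.null(y$power_sizes)) args$power_sizes <- as.integer(unlist(y$power_sizes))
  if (!is.null(y$cue)) args$cue <- do.call(cue_model_params, y$cue)
  if (!is.null(y$force)) {
    fargs <- y$force
    for (nm in c("peak_force_mean", "peak_force_sd")) {
      if (!is.null(fargs[[nm]])) fargs[[nm]] <- unlist(fargs[[nm]])
    }
    args$force <- do.call(force_model_params, fargs)
  }
  if (!is.null(y$between)) args$between <- y$between
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Simulates a dataset (unless one is supplied), preprocesses it, runs
#' the design-appropriate analysis, and (for study 1) estimates the
#' bootstrap power curve. Intermediates and a JSON report are written
#' under `out_dir` when given.
#'
#' @param config a `pipeline_config`.
#' @param trials optional pre-loaded trial table; when NULL a synthetic
#'   dataset is generated from the config.
#' @param out_dir optional output directory for the report bundle.
#' @param curve calibration curve.
#' @return list with `trials` (analysis-ready), `preprocess`
#'   (rejection report and exclusions), `analysis`, `power` (study 1
#'   only) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         out_dir = NULL, curve = default_calibration()) {
  .validate_config(config)
  if (is.null(trials)) {
    trials <- generate_dataset(config$n_participants, config$n_trials,
                               design = config$design, cue = config$cue,
                               force = config$force, between = config$between,
                               master_seed = config$master_seed, curve = curve)
  }
  pp <- tryCatch(
    preprocess(trials, curve, window_ms = config$window_ms,
               min_force = config$min_force,
               median_window = config$median_window, sd_mult = config$sd_mult,
               min_trials = config$min_trials, pre_cutoff = config$pre_cutoff),
    error = function(e) stop("preprocess stage failed: ", conditionMessage(e),
                             call. = FALSE))
  analysis <- tryCatch(
    if (config$design == "study1") {
      analyze_study1(pp$trials, n_boot = config$n_boot,
                     seed = config$master_seed)
    } else {
      analyze_study2(pp$trials)
    },
    error = function(e) stop("analyze stage failed: ", conditionMessage(e),
                             call. = FALSE))
  pw <- NULL
  if (config$design == "study1" && config$power_reps > 0) {
    stats_tbl <- power_cohort_stats(pp$trials)
    sizes <- config$power_sizes[config$power_sizes <= nrow(stats_tbl)]
    pw <- suppressWarnings(
      power_resample(stats_tbl, sizes = sizes, reps = config$power_reps,
                     alpha = config$power_alpha,
                     detector = config$power_detector,
                     seed = config$master_seed))
  }
  out <- list(trials = pp$trials,
              preprocess = list(report = pp$report,
                                exclusions = pp$exclusions),
              analysis = analysis, power = pw, config = config)
  if (!is.null(out_dir)) .write_report_bundle(out, out_dir)
  out
}

.write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dplyr::select(result$trials, -dplyr::any_of("trace")),
                   file.path(out_dir, "trials_preprocessed.csv"),
                   row.names = FALSE)
  utils::write.csv(result$preprocess$report,
                   file.path(out_dir, "filter_report.csv"), row.names = FALSE)
  report <- list(
    design = result$config$design,
    master_seed = result$config$master_seed,
    n_participants_analysed = length(unique(result$trials$participant_id)),
    exclusions = result$preprocess$exclusions,
    analysis = .jsonable(result$analysis),
    power = if (!is.null(result$power)) {
      list(curve = as.data.frame(result$power),
           min_n_0.8 = min_n_for_power(result$power, 0.8))
    },
    versions = list(r = as.character(getRversion()),
                    actbind = as.character(utils::packageVersion("actbind"))))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

.jsonable <- function(x) {
  if (inherits(x, "skipped_corr")) {
    return(list(r = x$r, n_used = x$n_used,
                outliers = x$outlier_indices, ci95 = x$ci95,
                p_onetailed_neg = x$p_onetailed_neg))
  }
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, .jsonable))
  x
}
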