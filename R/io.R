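.trial_schema <- c("participant_id", "study_tag", "condition",
                   "force_condition", "keypress_onset", "keypress_offset",
                   "reported_angle", "sound_onset", "trace")

#' Write and read trial tables
#'
#' Trial tables are stored as delimited text (CSV by default), one row
#' per trial; the force trace travels in a single JSON column
#' `trace` of the form `{"t0":0,"fs":518,"samples":[...]}` so that a
#' table is a self-contained plain-text artifact. The round trip
#' `read_trials(write_trials(x))` is lossless.
#'
#' @param trials a trial table (see [generate_dataset()] for the schema).
#' @param path file path.
#' @param sep field separator: `","` (CSV) or `"\t"` (TSV).
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a tibble in the canonical schema with a `force_trace`
#'   list-column.
#' @export
write_trials <- function(trials, path, sep = ",") {
  .check_trial_schema(trials, need_trace = TRUE)
  flat <- trials
  flat$trace <- vapply(trials$trace, function(tr) {
    jsonlite::toJSON(list(t0 = tr$t0, fs = tr$sampling_rate,
                          samples = tr$samples),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  utils::write.table(as.data.frame(flat)[, .trial_schema],
                     path, sep = sep, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, sep = ",") {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  .check_trial_schema(raw, need_trace = TRUE)
  raw$trace <- purrr::map(raw$trace, function(js) {
    p <- jsonlite::fromJSON(js)
    if (!all(c("t0", "fs", "samples") %in% names(p))) {
      stop("malformed trace payload: need fields t0, fs, samples",
           call. = FALSE)
    }
    structure(list(samples = as.integer(p$samples), t0 = p$t0,
                   sampling_rate = p$fs), class = "force_trace")
  })
  tibble::as_tibble(raw)
}

.check_trial_schema <- function(trials, need_trace = TRUE) {
  need <- .trial_schema
  if (!need_trace) need <- setdiff(need, "trace")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_cond <- setdiff(unique(trials$condition), c("AO", "AS"))
  if (length(bad_cond)) {
    stop("column `condition` contains invalid value(s): ",
         paste(bad_cond, collapse = ", "), call. = FALSE)
  }
  if (any(trials$reported_angle < 0 | trials$reported_angle >= 360)) {
    stop("column `reported_angle` must lie in [0, 360)", call. = FALSE)
  }
  invisible(trials)
}

#' Save and load calibration curves as JSON
#'
#' @param curve an `fsr_calibration`.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` an `fsr_calibration`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "fsr_calibration"))
  jsonlite::write_json(list(coef = curve$coef, degree = curve$degree,
                            raw_range = curve$raw_range,
                            anchors = curve$anchors),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(list(coef = as.numeric(p$coef), degree = as.integer(p$degree),
                 raw_range = as.numeric(p$raw_range),
                 anchors = as.data.frame(p$anchors)),
            class = "fsr_calibration")
}
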