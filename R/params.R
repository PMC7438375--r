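#' Cue-integration model parameters
#'
#' Parameters of the weighted multisensory model of reported action time.
#' The somatosensory cue time is tied to the force profile,
#' `S(F) = s_base + s_latency_gain * peak_latency(F)`, and the auditory
#' cue `A` is the (constant) action-effect delay. In the action-only
#' (AO) condition the report tracks the somatosensory cue alone
#' (`B1 = 1`); in the action-sound (AS) condition the report is the
#' weighted average `B1(F) * S + (1 - B1(F)) * A`, where the
#' somatosensory weight grows with peak force:
#' `B1(F) = 1 - weight_scale * exp(-weight_slope * F)`, clipped to
#' \[0, 1\]. Reports carry a trial-level Gaussian error and are quantized
#' to the Libet-clock resolution.
#'
#' @param sound_delay auditory action-effect delay in ms (default 250).
#' @param s_base baseline somatosensory cue latency (ms from keypress onset).
#' @param s_latency_gain dimensionless coupling of the somatosensory cue
#'   time to the peak-force latency.
#' @param weight_scale,weight_slope parameters of the force-dependent
#'   somatosensory weight `B1(F)`; `weight_slope > 0` makes stronger
#'   presses weight the somatosensory cue more.
#' @param report_bias constant report bias in ms.
#' @param report_noise_sd trial-level report noise SD in ms; a named
#'   vector with entries `free`, `light`, `strong` (strong presses give
#'   more precise reports), or a single value used everywhere.
#' @param clock_resolution report quantization step in ms (default 10:
#'   a 1800 ms clock period adjusted in 2 degree steps).
#' @return a list of class `cue_model_params`.
#' @examples
#' cue <- cue_model_params(report_noise_sd = 0)
#' somato_weight(c(0.5, 1.5, 3), cue)
#' @export
cue_model_params <- function(sound_delay = 250,
                             s_base = 0,
                             s_latency_gain = 0.6,
                             weight_scale = 0.35,
                             weight_slope = 1.0,
                             report_bias = 0,
                             report_noise_sd = c(free = 80, light = 80, strong = 72),
                             clock_resolution = 10) {
  if (length(report_noise_sd) == 1L && is.null(names(report_noise_sd))) {
    report_noise_sd <- c(free = report_noise_sd, light = report_noise_sd,
                         strong = report_noise_sd)
  }
  stopifnot(sound_delay >= 0, clock_resolution > 0,
            weight_scale >= 0, weight_slope >= 0,
            all(report_noise_sd >= 0),
            all(c("free", "light", "strong") %in% names(report_noise_sd)))
  structure(list(sound_delay = sound_delay, s_base = s_base,
                 s_latency_gain = s_latency_gain,
                 weight_scale = weight_scale, weight_slope = weight_slope,
                 report_bias = report_bias,
                 report_noise_sd = report_noise_sd,
                 clock_resolution = clock_resolution),
            class = "cue_model_params")
}

#' Somatosensory weight B1 as a function of peak force
#'
#' `B1(F) = 1 - weight_scale * exp(-weight_slope * F)`, clipped to
#' \[0, 1\]: non-decreasing in force, so stronger presses rely more on
#' the somatosensory cue and less on the delayed sound.
#'
#' @param force peak force in Newtons.
#' @param cue a [cue_model_params()] object.
#' @return weights in \[0, 1\], same length as `force`.
#' @export
somato_weight <- function(force, cue = cue_model_params()) {
  stopifnot(inherits(cue, "cue_model_params"))
  pmin(pmax(1 - cue$weight_scale * exp(-cue$weight_slope * force), 0), 1)
}

#' Keypress force-generation parameters
#'
#' Distributional parameters of simulated keypresses. Peak forces are
#' drawn per condition from truncated normal distributions: free presses
#' in the AS condition are lighter on average than in AO (distal
#' feedback reduces press intensity), and the `light`/`strong`
#' conditions are confined to the experimentally enforced acceptance
#' windows (raw 350-450 and 700-800, i.e. about 1.06-1.31 N and
#' 2.57-4.01 N). Peak-force latency increases with peak force
#' (`latency_gain > 0`), which is what makes the somatosensory cue of a
#' strong press arrive later; the defaults give a within-participant
#' force-latency correlation of about 0.23 for free pressing.
#'
#' @param peak_force_mean named vector of mean peak force (N) for
#'   `free_ao`, `free_as`, `light`, `strong`.
#' @param peak_force_sd named trial-level SD (N) for `free`, `light`,
#'   `strong`.
#' @param latency_intercept,latency_gain,latency_noise_sd linear model of
#'   peak-force latency (ms) on peak force (N): intercept, slope (ms/N)
#'   and trial-level noise SD.
#' @param trace_duration force-trace length in ms.
#' @param sampling_rate force-sensor sampling rate in Hz (default 518).
#' @param press_duration_mean,press_duration_sd registered key-contact
#'   duration (onset to offset), ms.
#' @param pulse_shape dimensionless shape exponent of the unimodal
#'   force pulse (larger = narrower).
#' @param trace_noise_sd sensor noise SD in raw FSR units.
#' @return a list of class `force_model_params`.
#' @export
force_model_params <- function(peak_force_mean = c(free_ao = 1.72, free_as = 1.44,
                                                   light = 1.18, strong = 3.10),
                               peak_force_sd = c(free = 0.50, light = 0.08,
                                                 strong = 0.30),
                               latency_intercept = 32,
                               latency_gain = 14,
                               latency_noise_sd = 30,
                               trace_duration = 1000,
                               sampling_rate = 518,
                               press_duration_mean = 149,
                               press_duration_sd = 25,
                               pulse_shape = 3,
                               trace_noise_sd = 1) {
  stopifnot(all(peak_force_mean > 0),
            all(c("free_ao", "free_as", "light", "strong") %in% names(peak_force_mean)),
            all(c("free", "light", "strong") %in% names(peak_force_sd)),
            latency_gain > 0, latency_noise_sd >= 0,
            trace_duration > 0, sampling_rate > 0,
            pulse_shape > 0, trace_noise_sd >= 0)
  structure(list(peak_force_mean = peak_force_mean,
                 peak_force_sd = peak_force_sd,
                 latency_intercept = latency_intercept,
                 latency_gain = latency_gain,
                 latency_noise_sd = latency_noise_sd,
                 trace_duration = trace_duration,
                 sampling_rate = sampling_rate,
                 press_duration_mean = press_duration_mean,
                 press_duration_sd = press_duration_sd,
                 pulse_shape = pulse_shape,
                 trace_noise_sd = trace_noise_sd),
            class = "force_model_params")
}

# truncated-normal draw by rejection with a safe fallback to the bounds
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  pmin(pmax(out, lower), upper)
}
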