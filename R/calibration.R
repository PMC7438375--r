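#' Force-sensor calibration: raw FSR units to Newtons
#'
#' A force sensing resistor (FSR) reports raw digitizer units in
#' \[0, 1023\]; the relationship between raw output and applied force is
#' monotone but nonlinear. `fit_calibration()` fits the lowest-degree
#' polynomial (degree at most `max_degree`) that passes within a relative
#' tolerance of a set of empirically measured anchor points and is
#' monotone non-decreasing over the anchored raw range. Raw values below
#' the first anchor are mapped by a linear segment through the origin
#' (sensor behaviour near zero is unspecified, so the conservative
#' extension is used).
#'
#' @param anchors data frame (or tibble) with numeric columns `raw` and
#'   `newton`; at least 3 rows, distinct `raw` values within \[0, 1023\].
#' @param tol relative tolerance at anchor points (default 0.05); an
#'   absolute tolerance of `tol` N applies where the anchor force is
#'   below 1 N.
#' @param max_degree highest polynomial degree tried (default 5).
#' @return an object of class `fsr_calibration` with elements `coef`
#'   (polynomial coefficients, intercept first), `degree`, `raw_range`
#'   (anchored raw range) and `anchors`.
#' @examples
#' cal <- fit_calibration(data.frame(raw = c(0, 500, 1000), newton = c(0, 1, 2)))
#' raw_to_newton(500, cal)
#' @export
fit_calibration <- function(anchors, tol = 0.05, max_degree = 5) {
  anchors <- as.data.frame(anchors)
  if (!all(c("raw", "newton") %in% names(anchors))) {
    stop("`anchors` must have columns `raw` and `newton`", call. = FALSE)
  }
  raw <- as.numeric(anchors$raw)
  nt <- as.numeric(anchors$newton)
  if (length(raw) < 3) stop("need at least 3 anchor points", call. = FALSE)
  if (anyDuplicated(raw)) stop("anchor raw values must be distinct", call. = FALSE)
  if (any(raw < 0 | raw > 1023)) stop("anchor raw values must lie in [0, 1023]", call. = FALSE)
  o <- order(raw)
  raw <- raw[o]; nt <- nt[o]
  if (any(diff(nt) < 0)) {
    stop("anchors are not monotone: no monotone calibration exists", call. = FALSE)
  }

  for (deg in seq_len(min(max_degree, length(raw) - 1L))) {
    cf <- stats::coef(stats::lm(nt ~ stats::poly(raw, deg, raw = TRUE)))
    cf[is.na(cf)] <- 0
    pred <- .poly_eval(raw, cf)
    err <- abs(pred - nt) / pmax(abs(nt), 1)
    if (any(err > tol)) next
    grid <- seq(min(raw), max(raw), length.out = 2048L)
    if (any(diff(.poly_eval(grid, cf)) < -1e-10)) next
    out <- structure(
      list(coef = unname(cf), degree = deg,
           raw_range = range(raw), anchors = data.frame(raw = raw, newton = nt)),
      class = "fsr_calibration")
    return(out)
  }
  stop("no monotone polynomial fit within tolerance at degrees 1..",
       min(max_degree, length(raw) - 1L), call. = FALSE)
}

.poly_eval <- function(x, coef) {
  out <- numeric(length(x))
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' @export
print.fsr_calibration <- function(x, ...) {
  cat("<fsr_calibration> degree", x$degree, "polynomial on raw range [",
      x$raw_range[1], ",", x$raw_range[2], "]\n")
  invisible(x)
}

#' Default FSR calibration curve
#'
#' Calibration through the origin and the four published anchor ranges of
#' the sensor: raw 350 and 450 map to 1.06 and 1.31 N (light-press
#' range), raw 700 and 800 to 2.57 and 4.01 N (strong-press range).
#'
#' @return an `fsr_calibration` object.
#' @export
default_calibration <- function() {
  fit_calibration(data.frame(
    raw = c(0, 350, 450, 700, 800),
    newton = c(0, 1.06, 1.31, 2.57, 4.01)))
}

#' Convert raw FSR readings to Newtons
#'
#' Applies the fitted calibration polynomial elementwise. Below the first
#' anchored raw value the curve is extended linearly through the origin,
#' which keeps the map monotone and maps raw 0 to 0 N.
#'
#' @param x numeric vector of raw readings in \[0, 1023\] (NA passed through).
#' @param curve an `fsr_calibration`, default [default_calibration()].
#' @return numeric vector of forces in Newtons.
#' @export
raw_to_newton <- function(x, curve = default_calibration()) {
  stopifnot(inherits(curve, "fsr_calibration"))
  x <- as.numeric(x)
  ok <- !is.na(x)
  if (any(x[ok] < 0 | x[ok] > 1023)) {
    stop("raw FSR values must lie in [0, 1023]", call. = FALSE)
  }
  lo <- curve$raw_range[1]
  out <- .poly_eval(x, curve$coef)
  if (lo > 0) {
    below <- ok & x < lo
    out[below] <- x[below] * (.poly_eval(lo, curve$coef) / lo)
  }
  out
}

#' Invert a calibration curve: Newtons to raw FSR units
#'
#' Numerical inverse of [raw_to_newton()] over the valid raw range,
#' used by the trace simulator. Forces above the value at raw = 1023 are
#' not representable.
#'
#' @param f numeric vector of forces in Newtons (non-negative).
#' @param curve an `fsr_calibration`.
#' @return numeric vector of (non-integer) raw units.
#' @export
newton_to_raw <- function(f, curve = default_calibration()) {
  stopifnot(inherits(curve, "fsr_calibration"))
  grid <- seq(0, 1023, by = 0.125)
  fn <- raw_to_newton(grid, curve)
  fmax <- fn[length(fn)]
  if (any(f < 0 | f > fmax, na.rm = TRUE)) {
    stop(sprintf("force outside representable range [0, %.3f] N", fmax),
         call. = FALSE)
  }
  # the calibration is monotone, so linear interpolation of the inverse
  # on a dense grid is accurate far below one raw quantization step
  stats::approx(fn, grid, xout = f, ties = "ordered")$y
}
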