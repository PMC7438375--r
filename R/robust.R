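#' Ideal fourths (interpolated quartiles)
#'
#' The quartile estimator used for boxplot fences in the robust
#' correlation: with `j = floor(n/4 + 5/12)` and
#' `h = n/4 + 5/12 - j`, the lower fourth is
#' `(1 - h) x(j) + h x(j+1)` and the upper fourth is its mirror image.
#'
#' @param x numeric vector (length >= 2, finite).
#' @return named numeric vector `c(lower = , upper = )`.
#' @keywords internal
ideal_fourths <- function(x) {
  x <- sort(x)
  n <- length(x)
  stopifnot(n >= 2)
  j <- floor(n / 4 + 5 / 12)
  h <- n / 4 + 5 / 12 - j
  lo <- (1 - h) * x[j] + h * x[j + 1]
  k <- n - j + 1
  hi <- (1 - h) * x[k] + h * x[k - 1]
  c(lower = lo, upper = hi)
}

.boxplot_flags <- function(v, k = 1.5) {
  q <- ideal_fourths(v)
  iqr <- q["upper"] - q["lower"]
  v < q["lower"] - k * iqr | v > q["upper"] + k * iqr
}

# robust per-coordinate scale: ideal-fourths IQR, falling back to the SD
# when more than half the values tie (keeps the outlier rule invariant
# under positive affine transforms of either axis)
.robust_scale <- function(v) {
  q <- ideal_fourths(v)
  s <- unname(q["upper"] - q["lower"])
  if (s <= 0) s <- stats::sd(v)
  s
}

# one pass of the projection outlier rule + Pearson on the survivors;
# returns NULL when the correlation is undefined on the retained points
.skipped_core <- function(x, y, fence_k = 1.5) {
  n <- length(x)
  dev <- cbind((x - stats::median(x)) / .robust_scale(x),
               (y - stats::median(y)) / .robust_scale(y))
  nrm <- sqrt(rowSums(dev^2))
  ok <- nrm > .Machine$double.eps
  flagged <- rep(FALSE, n)
  if (any(ok)) {
    units <- dev[ok, , drop = FALSE] / nrm[ok]
    proj <- dev %*% t(units) # column j: all points on direction of point j
    for (j in seq_len(ncol(proj))) {
      flagged <- flagged | .boxplot_flags(proj[, j], k = fence_k)
    }
  }
  keep <- which(!flagged)
  if (length(keep) < 3 ||
      stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
    return(NULL)
  }
  list(r = stats::cor(x[keep], y[keep]), flagged = flagged, keep = keep)
}

#' Skipped Pearson correlation
#'
#' Robust correlation that first removes bivariate outliers and then
#' computes the ordinary Pearson correlation on the remaining points.
#' Outliers are detected by outward projection: taking the
#' coordinatewise median as the robust center (after scaling each axis
#' by its ideal-fourths interquartile range, which makes the rule
#' invariant under positive affine transforms), every data point defines
#' a direction from the center; all points are projected onto each such
#' direction and a boxplot rule (ideal-fourths fences at `k = 1.5` IQR)
#' flags extreme projections. A point flagged on any direction is an
#' outlier. When no point is flagged the result equals the plain Pearson
#' correlation. The confidence interval is a percentile bootstrap of the
#' whole procedure: each resample of the original pairs is re-screened
#' for outliers before its correlation enters the bootstrap
#' distribution.
#'
#' @param x,y numeric vectors of equal length (finite values).
#' @param min_n minimum sample size (default 10).
#' @param n_boot bootstrap resamples for the CI (default 1000; 0 skips
#'   the CI).
#' @param conf confidence level (default 0.95).
#' @param fence_k boxplot fence constant of the outlier rule (default
#'   1.5; recorded in the result so rule variants stay identifiable).
#' @param seed optional integer seed for the bootstrap.
#' @return an object of class `skipped_corr`: list with `r`, `n_used`,
#'   `outlier_indices`, `ci95` (or NULL), `n_boot`, and `p_onetailed_neg`
#'   / `p_twotailed` from the t approximation on the retained pairs.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- x + rnorm(30)
#' skipped_pearson(x, y, n_boot = 0)
#' @export
skipped_pearson <- function(x, y, min_n = 10, n_boot = 1000, conf = 0.95,
                            fence_k = 1.5, seed = NULL) {
  stopifnot(length(x) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  n <- length(x)
  if (n < min_n) {
    stop(sprintf("need at least %d points, got %d", min_n, n), call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance after outlier removal",
         call. = FALSE)
  }
  core <- .skipped_core(x, y, fence_k)
  if (is.null(core)) {
    stop("correlation undefined: zero variance after outlier removal",
         call. = FALSE)
  }
  r <- core$r
  df <- length(core$keep) - 2
  tstat <- r * sqrt(df / (1 - r^2))
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    rb <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- .skipped_core(x[idx], y[idx], fence_k)
      if (is.null(res)) NA_real_ else res$r
    }, numeric(1))
    rb <- rb[is.finite(rb)]
    ci <- unname(stats::quantile(rb, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(r = r, n_used = length(core$keep),
                 outlier_indices = which(core$flagged),
                 ci95 = ci, n_boot = n_boot, fence_k = fence_k,
                 p_twotailed = 2 * stats::pt(-abs(tstat), df),
                 p_onetailed_neg = stats::pt(tstat, df)),
            class = "skipped_corr")
}

#' @export
print.skipped_corr <- function(x, ...) {
  cat(sprintf("<skipped_corr> r = %.3f on %d points (%d outlier%s removed)\n",
              x$r, x$n_used, length(x$outlier_indices),
              if (length(x$outlier_indices) == 1) "" else "s"))
  if (!is.null(x$ci95)) {
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f] (%d resamples)\n",
                x$ci95[1], x$ci95[2], x$n_boot))
  }
  invisible(x)
}

#' Group-level test of per-participant correlation coefficients
#'
#' One-sample t test comparing the mean of per-participant correlation
#' coefficients (on the raw r scale) against `mu0`, two-tailed, with the
#' within-subject effect size `dz = mean / SD`.
#'
#' @param r numeric vector of per-participant coefficients (>= 3).
#' @param mu0 null value (default 0).
#' @return tibble with `mean`, `sd`, `n`, `t`, `df`, `p` (two-tailed)
#'   and `dz`.
#' @export
group_corr_test <- function(r, mu0 = 0) {
  r <- r[is.finite(r)]
  if (length(r) < 3) stop("need at least 3 coefficients", call. = FALSE)
  if (stats::sd(r) == 0) {
    stop("degenerate test: coefficients have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(r, mu = mu0)
  tibble::tibble(mean = mean(r), sd = stats::sd(r), n = length(r),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, dz = (mean(r) - mu0) / stats::sd(r))
}

#' Normality tests: Lilliefors and Jarque-Bera
#'
#' `lilliefors_test()` is the Kolmogorov-Smirnov test against a normal
#' distribution with estimated mean and SD; the p-value comes from a
#' seeded Monte-Carlo null (default 10^4 simulations) or, with
#' `n_sim = 0`, from the Dallal-Wilkinson approximation
#' (via \pkg{nortest}). `jarque_bera_test()` uses
#' `JB = n/6 (skew^2 + (kurt - 3)^2 / 4)` with a chi-squared(2)
#' reference, or a Monte-Carlo null for small samples.
#'
#' @param x numeric vector (n >= 4 for Lilliefors).
#' @param n_sim Monte-Carlo simulations of the null (0 = analytic p).
#' @param seed integer seed for the Monte-Carlo null.
#' @return tibble with `statistic` and `p`.
#' @export
lilliefors_test <- function(x, n_sim = 10000, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input: zero variance", call. = FALSE)
  stat <- .lillie_stat(x)
  if (n_sim > 0) {
    set.seed(seed)
    null <- vapply(seq_len(n_sim), function(i) .lillie_stat(stats::rnorm(n)),
                   numeric(1))
    p <- (1 + sum(null >= stat)) / (n_sim + 1)
  } else {
    p <- nortest::lillie.test(x)$p.value
  }
  tibble::tibble(statistic = stat, p = p)
}

.lillie_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(max(i / n - z), max(z - (i - 1) / n))
}

#' @rdname lilliefors_test
#' @export
jarque_bera_test <- function(x, n_sim = 0, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate input: zero variance", call. = FALSE)
  stat <- .jb_stat(x)
  if (n_sim > 0) {
    set.seed(seed)
    null <- vapply(seq_len(n_sim), function(i) .jb_stat(stats::rnorm(n)),
                   numeric(1))
    p <- (1 + sum(null >= stat)) / (n_sim + 1)
  } else {
    p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, p = p)
}

.jb_stat <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  n / 6 * (skew^2 + (kurt - 3)^2 / 4)
}
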