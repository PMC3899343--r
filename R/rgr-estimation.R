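#' Log transform of count data
#'
#' `ln(n + 1)` elementwise: the shift keeps zero counts (common at season
#' edges) defined, and those runs are deliberately retained rather than
#' trimmed.
#'
#' @param counts non-negative numeric vector.
#' @return `log(counts + 1)`.
#' @export
log_transform <- function(counts) {
  if (any(counts < 0)) stop("negative count")
  log1p(counts)
}

#' Fit a cross-validated cubic smoothing spline
#'
#' Fits a penalized cubic smoothing spline to `(times, y)` with the
#' smoothing penalty selected by ordinary leave-one-out cross-validation:
#' the LOO prediction squared error is evaluated on a grid of 50 `spar`
#' values (equally spaced in `spar`, i.e. log-spaced in the penalty
#' \eqn{\lambda}, spanning the near-interpolation to the near-linear
#' regime) and the grid optimum is refined by golden-section search
#' between its neighbouring grid points.  Formulations of the LOO
#' criterion differ only in sign convention; here the prediction squared
#' error is minimized.  If the optimum sits on the grid boundary a warning
#' is raised.
#'
#' The spline engine is [stats::smooth.spline()]; the returned object
#' carries its B-spline representation (knots and coefficients), which is
#' evaluable and differentiable everywhere on the data range.
#'
#' @param times numeric time points (days); at least 4 distinct values,
#'   no duplicates (aggregate first if needed).
#' @param y response values (typically `ln(count + 1)`).
#' @param spar_grid grid of `spar` values scanned for the CV optimum.
#' @return An object of class `"spline_fit"`: list with elements `spline`
#'   (the `smooth.spline` object), `spar`, `lambda` (the penalty),
#'   `cv_score` (LOO criterion at the optimum), `boundary` (logical) and
#'   `range` (fitted time range).
#' @export
fit_smoothing_spline <- function(times, y,
                                 spar_grid = seq(-1.5, 2.5,
                                                 length.out = 50)) {
  if (length(times) != length(y)) stop("times and y lengths differ")
  if (anyDuplicated(times)) stop("duplicate times; aggregate first")
  if (length(unique(times)) < 4L) stop("need at least 4 distinct time points")
  cv_at <- function(sp) {
    f <- tryCatch(stats::smooth.spline(times, y, spar = sp, cv = TRUE),
                  error = function(e) NULL,
                  warning = function(w) suppressWarnings(
                    stats::smooth.spline(times, y, spar = sp, cv = TRUE)))
    if (is.null(f) || !is.finite(f$cv.crit)) Inf else f$cv.crit
  }
  scores <- vapply(spar_grid, cv_at, numeric(1))
  if (all(!is.finite(scores))) {
    # degenerate (e.g. constant) data: every penalty reproduces the data;
    # take the smoothest grid point
    best_spar <- spar_grid[length(spar_grid)]
    warning("cross-validation criterion degenerate; using smoothest penalty")
  } else {
    i <- which.min(scores)
    if (i == 1L || i == length(spar_grid)) {
      warning("cross-validation optimum at the boundary of the penalty grid")
      best_spar <- spar_grid[i]
    } else {
      best_spar <- stats::optimize(cv_at,
                                   c(spar_grid[i - 1L], spar_grid[i + 1L]),
                                   tol = 1e-4)$minimum
      if (cv_at(best_spar) > scores[i]) best_spar <- spar_grid[i]
    }
  }
  fit <- suppressWarnings(
    stats::smooth.spline(times, y, spar = best_spar, cv = TRUE))
  structure(list(spline = fit, spar = best_spar, lambda = fit$lambda,
                 cv_score = fit$cv.crit, range = range(times)),
            class = "spline_fit")
}

#' Analytic derivative of a fitted smoothing spline
#'
#' Evaluates the exact derivative of the fitted piecewise cubic (via its
#' B-spline representation, not finite differences) at the requested
#' times.  Extrapolation beyond the fitted range is refused.
#'
#' @param fit a [fit_smoothing_spline()] result.
#' @param at evaluation times, inside the fitted range.
#' @return Numeric vector of slopes (response units per day).
#' @export
spline_derivative <- function(fit, at) {
  stopifnot(inherits(fit, "spline_fit"))
  if (any(at < fit$range[1] | at > fit$range[2]))
    stop("extrapolation outside the fitted time range")
  stats::predict(fit$spline, at, deriv = 1)$y
}

#' @export
predict.spline_fit <- function(object, at = NULL, deriv = 0, ...) {
  if (is.null(at)) at <- object$spline$x
  stats::predict(object$spline, at, deriv = deriv)$y
}

#' Estimate the observed RGR series of a field survey
#'
#' The instantaneous relative growth rate at each sampling date is the
#' logarithmic derivative of the smoothed abundance curve, obtained in
#' three steps: (1) transform the counts to `ln(n + 1)`; (2) smooth the
#' log series with a cubic smoothing spline whose penalty is selected by
#' leave-one-out cross-validation ([fit_smoothing_spline()]); (3) evaluate
#' the analytic derivative of the spline at the sampling dates
#' ([spline_derivative()]).  The result is in aphids per aphid per day
#' (1/day).
#'
#' @param survey a [field_survey()] with at least 4 sampling dates.
#' @param counts which count series to smooth: `"total"` (default; the
#'   raw total over the inspected tillers, the natural scale for count
#'   noise) or `"density"` (aphids per tiller; useful when sampling effort
#'   varies strongly between dates).
#' @param dense_grid if `TRUE`, also return a daily grid of the smoothed
#'   curve and its derivative (for plotting; not used in fitting).
#' @return A data frame of class `"rgr_series"` with columns `date`,
#'   `rgr`, `log_count`, and attributes `smoothing_parameter` (the
#'   penalty `lambda`), `spar`, `cv_score`, `field_id` and (if requested)
#'   `dense` (a data frame `time`, `smooth`, `rgr`).
#' @examples
#' s <- simulate_fields(n_fields = 1, seed = 42)$surveys[[1]]
#' estimate_rgr(s)
#' @export
estimate_rgr <- function(survey, counts = c("total", "density"),
                         dense_grid = FALSE) {
  stopifnot(inherits(survey, "field_survey"))
  counts <- match.arg(counts)
  if (nrow(survey) < 4L) stop("need at least 4 sampling dates")
  tt <- as.numeric(survey$date - survey$date[1])
  y <- log_transform(if (counts == "total") survey$aphids else survey$density)
  fit <- fit_smoothing_spline(tt, y)
  rgr <- spline_derivative(fit, tt)
  out <- structure(
    data.frame(date = survey$date, rgr = rgr, log_count = y),
    smoothing_parameter = fit$lambda, spar = fit$spar,
    cv_score = fit$cv_score, field_id = attr(survey, "field_id"),
    counts = counts,
    class = c("rgr_series", "data.frame"))
  if (dense_grid) {
    tg <- seq(tt[1], tt[length(tt)], by = 1)
    attr(out, "dense") <- data.frame(
      time = tg,
      smooth = predict(fit, tg),
      rgr = spline_derivative(fit, tg))
  }
  out
}

#' @export
print.rgr_series <- function(x, ...) {
  cat("RGR series (", attr(x, "field_id"), "): ", nrow(x),
      " dates, lambda = ", format(attr(x, "smoothing_parameter"),
                                  digits = 4),
      ", range [", format(min(x$rgr), digits = 3), ", ",
      format(max(x$rgr), digits = 3), "] /day\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
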