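#' Parameters of the aphid RGR response surface
#'
#' Container for the parameter vector of the deterministic relative growth
#' rate surface \eqn{f(\theta, s)} of [rgr_surface()].  Two quantities are
#' biological constants fixed before fitting: the lethal maximum
#' temperature `theta_max` (30 degrees C, above which aphid RGR cannot be
#' positive) and the terminal wheat stage `s_max` (Zadoks 92, grain
#' ripening, after which the crop no longer supports aphid feeding).  Four
#' are free parameters estimated from data: `s_m` (Zadoks position of the
#' left inflexion of the stage response), `a` (overall scale, 1/day per
#' temperature-response unit), `b` (temperature-shape exponent) and `k`
#' (steepness of the stage sigmoid, per Zadoks unit).  `tau` is a fixed
#' numerical constant (Zadoks units) controlling how fast the surface
#' collapses as `s` approaches `s_max`; it is not fitted, preserving the
#' four-parameter structure of the model.
#'
#' The optional `c_E` and `c_M` extend the surface linearly with
#' natural-enemy pressure; see [rgr_with_enemies()].
#'
#' @param s_m left inflexion of the stage response, `0 < s_m < s_max`.
#' @param a scale parameter, `a >= 0`.
#' @param b temperature-shape exponent, `b > 0`.
#' @param k stage-sigmoid steepness, `k > 0` (per Zadoks unit).
#' @param theta_max lethal maximum temperature (degrees C), default 30.
#' @param s_max terminal Zadoks stage, default 92.
#' @param tau right-edge collapse scale (Zadoks units), fixed, default 2.
#' @param c_E,c_M optional linear coefficients (1/day per counted
#'   fungus-killed aphid / mummy); both or neither.
#' @return An object of class `"rgr_params"`.
#' @examples
#' p <- rgr_params(s_m = 45, a = 0.02, b = 1.2, k = 0.35)
#' rgr_surface(15, 55, p)
#' @export
rgr_params <- function(s_m, a, b, k, theta_max = 30, s_max = 92, tau = 2,
                       c_E = NULL, c_M = NULL) {
  if (theta_max <= 0) stop("theta_max must be positive")
  if (s_max <= 0 || s_max > 99) stop("s_max must be in (0, 99]")
  if (s_m <= 0 || s_m >= s_max) stop("s_m must be in (0, s_max)")
  if (a < 0) stop("a must be >= 0")
  if (b <= 0) stop("b must be > 0")
  if (k <= 0) stop("k must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  if (is.null(c_E) != is.null(c_M))
    stop("c_E and c_M must be both present or both absent")
  structure(list(theta_max = theta_max, s_max = s_max, s_m = s_m,
                 a = a, b = b, k = k, tau = tau, c_E = c_E, c_M = c_M),
            class = "rgr_params")
}

#' @export
print.rgr_params <- function(x, digits = 4, ...) {
  cat("RGR surface parameters\n")
  cat("  fixed:  theta_max =", x$theta_max, " s_max =", x$s_max,
      " tau =", x$tau, "\n")
  cat("  free:   s_m =", signif(x$s_m, digits), " b =", signif(x$b, digits),
      " k =", signif(x$k, digits), " a =", signif(x$a, digits), "\n")
  if (!is.null(x$c_E))
    cat("  enemy:  c_E =", signif(x$c_E, digits),
        " c_M =", signif(x$c_M, digits), "\n")
  invisible(x)
}

#' Deterministic RGR response surface
#'
#' The relative growth rate (1/day) of an aphid population as a function of
#' mean temperature `theta` (degrees C) and Zadoks wheat stage `s`:
#'
#' \deqn{f(\theta, s) = a\,\theta^{b}\,\frac{\theta_{max}-\theta}{\theta_{max}}
#'   \cdot \frac{1}{1+e^{-k (s - s_m)}}
#'   \cdot \left(1 - e^{-(s_{max}-s)/\tau}\right)}
#'
#' for `0 < theta < theta_max` and `0 <= s < s_max`, and 0 otherwise.
#' The temperature factor rises like a power law and is pulled down
#' linearly towards the lethal maximum, giving a single interior thermal
#' optimum at \eqn{\theta^\ast = b\,\theta_{max}/(b+1)}; the stage response
#' is sigmoidal on the left (inflexion at `s_m`, reflecting crop
#' colonisation and improving host quality up to heading) and collapses
#' over the last few Zadoks units before grain ripening (`s_max`), where
#' declining nutrient quality drives emigration and reproductive shutdown.
#'
#' @param theta temperature(s), degrees C; finite.
#' @param s Zadoks stage(s) in `[0, 99]`; recycled against `theta`.
#' @param params an [rgr_params()] object.
#' @return Numeric vector of RGR values (1/day).
#' @examples
#' p <- rgr_params(s_m = 45, a = 0.02, b = 1.2, k = 0.35)
#' rgr_surface(c(10, 20, 30), 60, p)   # 0 at the lethal maximum
#' @export
rgr_surface <- function(theta, s, params) {
  stopifnot(inherits(params, "rgr_params"))
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (any(s < 0 | s > 99)) stop("Zadoks stage outside [0, 99]")
  surface_eval(theta, s, params)
}

# unvalidated core evaluator; `params` is any list with the surface
# fields (used with perturbed values by the numeric Jacobian)
surface_eval <- function(theta, s, params) {
  n <- max(length(theta), length(s))
  theta <- rep_len(theta, n); s <- rep_len(s, n)
  out <- numeric(n)
  live <- theta > 0 & theta < params$theta_max & s < params$s_max
  th <- theta[live]; ss <- s[live]
  out[live] <- params$a * th^params$b * (params$theta_max - th) / params$theta_max *
    stats::plogis(params$k * (ss - params$s_m)) *
    (1 - exp(-(params$s_max - ss) / params$tau))
  out
}

#' RGR surface with linear natural-enemy terms
#'
#' Extends [rgr_surface()] with a linear dependence on the per-sample
#' counts of fungus-killed aphids (`E`) and parasitoid mummies (`M`):
#' \eqn{f(\theta, s) + c_E E + c_M M}.  Both coefficients must be present
#' in `params`; they are usually negative (enemy pressure reduces growth).
#'
#' @inheritParams rgr_surface
#' @param E,M non-negative enemy counts, recycled.
#' @return Numeric vector of RGR values (1/day).
#' @export
rgr_with_enemies <- function(theta, s, E, M, params) {
  stopifnot(inherits(params, "rgr_params"))
  if (is.null(params$c_E) || is.null(params$c_M))
    stop("params lack enemy coefficients c_E / c_M")
  if (any(E < 0) || any(M < 0)) stop("enemy counts must be non-negative")
  rgr_surface(theta, s, params) + params$c_E * E + params$c_M * M
}

#' Evaluate the RGR surface on a rectangular grid
#'
#' Convenience evaluation for prediction maps: a grid of temperatures by
#' stages, with the coordinates returned alongside the matrix.
#'
#' @param params an [rgr_params()] object.
#' @param theta_range,s_range length-2 numeric ranges (non-degenerate).
#' @param resolution number of grid points per axis; scalar or length 2
#'   `(theta, s)`.
#' @return A list of class `"rgr_grid"`: `theta` (row coordinates),
#'   `stage` (column coordinates) and `rgr` (matrix, rows = temperatures).
#' @export
prediction_grid <- function(params, theta_range = c(0, 30),
                            s_range = c(30, 92), resolution = 50) {
  if (length(resolution) == 1L) resolution <- rep(resolution, 2L)
  if (any(resolution < 1)) stop("resolution must be >= 1")
  if (diff(theta_range) < 0 || diff(s_range) < 0)
    stop("degenerate range")
  th <- seq(theta_range[1], theta_range[2], length.out = resolution[1])
  ss <- seq(s_range[1], s_range[2], length.out = resolution[2])
  z <- outer(th, ss, function(a, b) rgr_surface(a, b, params))
  dimnames(z) <- list(theta = signif(th, 6), stage = signif(ss, 6))
  structure(list(theta = th, stage = ss, rgr = z), class = "rgr_grid")
}

# free parameters of the surface, in the reporting order used for
# correlation tables: s_m, b, k, a (then enemy coefficients)
free_param_names <- function(with_enemies = FALSE) {
  c("s_m", "b", "k", "a", if (with_enemies) c("c_E", "c_M"))
}

#' Serialize / deserialize RGR parameters
#'
#' Flat key-value representation used in config files and fit output.
#'
#' @param params an [rgr_params()] object.
#' @return `params_to_list()`: a named list; `params_from_list()`: an
#'   [rgr_params()] object.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "rgr_params"))
  out <- params[!vapply(params, is.null, logical(1))]
  class(out) <- NULL
  out
}

#' @rdname params_to_list
#' @param x a named list with at least `s_m`, `a`, `b`, `k`.
#' @export
params_from_list <- function(x) {
  do.call(rgr_params, x[intersect(names(x),
    c("s_m", "a", "b", "k", "theta_max", "s_max", "tau", "c_E", "c_M"))])
}
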