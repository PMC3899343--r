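#' Weekly mean of mean daily temperatures
#'
#' For each anchor date, the arithmetic mean of `t_mean` over the trailing
#' 7-day window ending at (and including) the anchor.  Windows with fewer
#' than 7 available days use the days present and raise a warning; windows
#' with no days at all yield `NA`.
#'
#' @param temps a [temperature_series()].
#' @param week_anchors `Date` vector of (typically weekly) sampling dates.
#' @return Numeric vector, one weekly mean per anchor (degrees C).
#' @export
weekly_mean_temperature <- function(temps, week_anchors) {
  stopifnot(inherits(temps, "temperature_series"))
  week_anchors <- as.Date(week_anchors)
  short <- 0L
  out <- vapply(week_anchors, function(a) {
    w <- temps$t_mean[temps$date > a - 7 & temps$date <= a]
    if (length(w) == 0L) return(NA_real_)
    if (length(w) < 7L) short <<- short + 1L
    mean(w)
  }, numeric(1))
  if (short > 0L)
    warning(short, " window(s) had fewer than 7 daily records; ",
            "mean taken over available days")
  out
}

#' Pool surveys into a regression dataset
#'
#' Builds one record per (field, sampling date): the estimated RGR
#' response, the weekly mean temperature over the trailing week, the
#' Zadoks stage, and enemy counts when the survey carries them.  Dates
#' whose trailing week has no temperature coverage are dropped with a
#' message.  Records are sorted by field then date, so the result does
#' not depend on the order the fields are supplied in.
#'
#' @param surveys list of [field_survey()] objects.
#' @param rgr_list list of matching [estimate_rgr()] results (same order
#'   and lengths as `surveys`).
#' @param temps either a single [temperature_series()] shared by all
#'   fields or a list with one series per survey.
#' @return A data frame of class `"rgr_dataset"` with columns `field_id`,
#'   `date`, `rgr_obs`, `theta`, `stage` and, when every survey has them,
#'   `e_kills` and `mummies`.
#' @export
build_dataset <- function(surveys, rgr_list, temps) {
  if (inherits(surveys, "field_survey")) surveys <- list(surveys)
  if (inherits(rgr_list, "rgr_series")) rgr_list <- list(rgr_list)
  if (length(surveys) != length(rgr_list))
    stop("surveys and rgr_list must be aligned lists of equal length")
  if (inherits(temps, "temperature_series"))
    temps <- rep(list(temps), length(surveys))
  if (length(temps) != length(surveys))
    stop("temps must be one series or one per survey")
  all_enemies <- all(vapply(surveys, has_enemies, logical(1)))
  recs <- vector("list", length(surveys))
  dropped <- 0L
  for (i in seq_along(surveys)) {
    sv <- surveys[[i]]; rg <- rgr_list[[i]]
    if (nrow(sv) != nrow(rg) || any(sv$date != rg$date))
      stop("survey and RGR series misaligned for field ",
           attr(sv, "field_id"))
    theta <- weekly_mean_temperature(temps[[i]], sv$date)
    keep <- is.finite(theta)
    dropped <- dropped + sum(!keep)
    d <- data.frame(field_id = attr(sv, "field_id"),
                    date = sv$date, rgr_obs = rg$rgr,
                    theta = theta, stage = sv$stage)
    if (all_enemies) { d$e_kills <- sv$e_kills; d$mummies <- sv$mummies }
    recs[[i]] <- d[keep, , drop = FALSE]
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$field_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  if (dropped > 0L)
    message(dropped, " record(s) dropped for missing temperature coverage")
  structure(out, class = c("rgr_dataset", "data.frame"))
}

# model prediction for a free-parameter vector on a dataset (no
# validation: the numeric Jacobian probes slightly outside the bounds)
predict_free <- function(phi, data, fixed, with_enemies) {
  p <- list(s_m = phi[["s_m"]], a = phi[["a"]], b = phi[["b"]],
            k = phi[["k"]],
            theta_max = fixed$theta_max, s_max = fixed$s_max,
            tau = fixed$tau)
  out <- surface_eval(data$theta, data$stage, p)
  if (with_enemies)
    out <- out + phi[["c_E"]] * data$e_kills + phi[["c_M"]] * data$mummies
  out
}

# projection of the free-parameter vector onto its feasible box;
# enemy coefficients are unconstrained
project_free <- function(phi, fixed) {
  phi[["s_m"]] <- min(max(phi[["s_m"]], 1e-6), fixed$s_max - 1e-6)
  phi[["a"]] <- max(phi[["a"]], 0)
  phi[["b"]] <- max(phi[["b"]], 1e-6)
  phi[["k"]] <- max(phi[["k"]], 1e-6)
  phi
}

# one optimisation run from a single start; method "gn" is Gauss-Newton
# with step-halving and bound projection, "lm" is Levenberg-Marquardt
fit_one_start <- function(phi, y, data, fixed, with_enemies, opts, sse,
                          nm, p) {
  obj <- sse(phi)
  converged <- FALSE; msg <- "ok"; iter <- 0L
  if (opts$method == "lm") {
    lm_fit <- minpack.lm::nls.lm(
      par = phi,
      fn = function(ph) y - predict_free(project_free(ph, fixed), data,
                                         fixed, with_enemies),
      control = minpack.lm::nls.lm.control(maxiter = opts$max_iter))
    phi <- project_free(stats::coef(lm_fit), fixed)
    obj <- sse(phi); iter <- lm_fit$niter
    converged <- lm_fit$info %in% 1:4
    msg <- lm_fit$message
  } else {
    lo <- c(s_m = 1e-6, b = 1e-6, k = 1e-6, a = 0,
            c_E = -Inf, c_M = -Inf)[nm]
    hi <- c(s_m = fixed$s_max - 1e-6, b = Inf, k = Inf, a = Inf,
            c_E = Inf, c_M = Inf)[nm]
    for (iter in seq_len(opts$max_iter)) {
      r <- y - predict_free(phi, data, fixed, with_enemies)
      J <- num_jacobian(phi, data, fixed, with_enemies)
      qrJ <- qr(J)
      if (qrJ$rank < p) {
        cc <- suppressWarnings(stats::cor(J))
        diag(cc) <- 0
        worst <- which(abs(cc) == max(abs(cc), na.rm = TRUE),
                       arr.ind = TRUE)[1, ]
        stop("singular Jacobian: parameters '", nm[worst[1]], "' and '",
             nm[worst[2]], "' are numerically collinear")
      }
      delta <- qr.coef(qrJ, r)
      # freeze components pushing outward at an active bound, and cap the
      # step at the first bound crossing rather than clamping through it
      delta[(phi - lo < 1e-12 & delta < 0) |
            (hi - phi < 1e-12 & delta > 0)] <- 0
      if (all(delta == 0)) { converged <- TRUE; msg <- "active bounds"; break }
      head <- rep(Inf, p)
      head[delta < 0] <- (phi - lo)[delta < 0] / -delta[delta < 0]
      head[delta > 0] <- (hi - phi)[delta > 0] / delta[delta > 0]
      alpha <- min(1, 0.999 * min(head))
      new_obj <- Inf; cand <- phi
      repeat {
        cand <- project_free(phi + alpha * delta, fixed)
        new_obj <- sse(cand)
        if (new_obj <= obj || alpha < 2^-30) break
        alpha <- alpha / 2
      }
      if (new_obj > obj) { msg <- "step-halving stalled"; break }
      rel <- (obj - new_obj) / max(obj, .Machine$double.eps)
      phi <- cand; obj <- new_obj
      if (rel < opts$tol) { converged <- TRUE; break }
    }
    if (!converged && msg == "ok") msg <- "max iterations reached"
  }
  list(phi = phi, obj = obj, converged = converged, iter = iter, msg = msg)
}

# central-difference Jacobian of the model prediction
num_jacobian <- function(phi, data, fixed, with_enemies) {
  J <- matrix(0, nrow(data), length(phi),
              dimnames = list(NULL, names(phi)))
  for (j in seq_along(phi)) {
    h <- 1e-6 * max(1, abs(phi[[j]]))
    up <- dn <- phi
    up[[j]] <- phi[[j]] + h; dn[[j]] <- phi[[j]] - h
    J[, j] <- (predict_free(up, data, fixed, with_enemies) -
               predict_free(dn, data, fixed, with_enemies)) / (2 * h)
  }
  J
}

# default starting values: s_m at a stage quantile, unit temperature
# exponent, moderate sigmoid steepness, and a scaled so the surface
# maximum over the observed design matches the 95th percentile of the
# observed RGR
default_init <- function(data, fixed, s_m_quantile = 0.5, k = 0.3,
                         b = 1) {
  phi <- c(s_m = stats::quantile(data$stage, s_m_quantile, names = FALSE),
           b = b, k = k, a = 1)
  g <- predict_free(phi, data, fixed, with_enemies = FALSE)
  top <- max(g)
  q95 <- stats::quantile(data$rgr_obs, 0.95, names = FALSE)
  phi[["a"]] <- if (top > 0 && q95 > 0) q95 / top else 0.01
  phi
}

#' Fit the RGR response surface by nonlinear least squares
#'
#' Estimates the free parameters (`s_m`, `b`, `k`, `a`, plus `c_E`, `c_M`
#' when `with_enemies = TRUE`) by minimising the residual sum of squares
#' of the observed RGR against the surface, using Gauss-Newton iterations
#' with step-halving: at each iteration the linearised least-squares step
#' is computed from a central-difference Jacobian and halved until the
#' objective decreases, with parameters projected back onto their bounds
#' (`0 < s_m < s_max`, `a >= 0`, `b, k > 0`).  Convergence is declared
#' when the relative objective decrease falls below `tol` (default 1e-8)
#' or after `max_iter` (default 200) iterations; failure to converge sets
#' a flag rather than raising an error.  `method = "lm"` instead uses
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]), useful when Gauss-Newton
#' stalls on difficult data.  When no `init` is given the objective --
#' which can be multimodal in `s_m` -- is optimised from three starting
#' points (`s_m` at the 25th, 50th and 75th stage percentiles) and the
#' best optimum is kept.
#'
#' Asymptotic parameter correlations are computed from the inverse
#' cross-product of the final Jacobian; the strong `a`-`b` correlation
#' typical of power-law temperature responses shows up there.
#'
#' @param data an [build_dataset()] result (needs `n > p` records).
#' @param init optional named starting vector (`s_m`, `b`, `k`, `a`, and
#'   `c_E`, `c_M` if applicable); sensible defaults otherwise.
#' @param fixed list of fixed constants `theta_max`, `s_max` (and
#'   optionally `tau`).
#' @param with_enemies include the linear enemy terms (requires enemy
#'   columns in `data`).
#' @param options list: `max_iter`, `tol`, `method` (`"gn"` or `"lm"`).
#' @return An object of class `"rgr_fit"`: `params` ([rgr_params()]),
#'   `estimates` (named free-parameter vector), `fitted`, `residuals`,
#'   `correlation` (asymptotic correlation matrix in the order `s_m`,
#'   `b`, `k`, `a`, ...), `std_errors`, `convergence` (list: `converged`,
#'   `iterations`, `objective`, `method`, `message`), `n`, `p`, and the
#'   `data` used.
#' @export
fit_rgr_model <- function(data, init = NULL,
                          fixed = list(theta_max = 30, s_max = 92, tau = 2),
                          with_enemies = FALSE, options = list()) {
  stopifnot(inherits(data, "data.frame"))
  opts <- utils::modifyList(
    list(max_iter = 200L, tol = 1e-8, method = "gn"), options)
  if (is.null(fixed$tau)) fixed$tau <- 2
  if (with_enemies && (is.null(data$e_kills) || is.null(data$mummies)))
    stop("with_enemies = TRUE requires e_kills and mummies columns")
  nm <- free_param_names(with_enemies)
  n <- nrow(data); p <- length(nm)
  if (n <= p) stop("need more records (", n, ") than free parameters (",
                   p, ")")
  starts <- if (is.null(init)) {
    # the objective can be multimodal in s_m, k and b; start from a small
    # grid (stage quantiles x sigmoid steepness x temperature exponent)
    # and keep the best optimum
    grid <- expand.grid(q = c(0.5, 0.25, 0.75), k = c(0.3, 0.7),
                        b = c(1, 0.3))
    lapply(seq_len(nrow(grid)), function(i) {
      st <- default_init(data, fixed, grid$q[i], grid$k[i],
                         grid$b[i])[c("s_m", "b", "k", "a")]
      if (with_enemies) st <- c(st, c_E = 0, c_M = 0)
      st
    })
  } else {
    if (!all(nm %in% names(init))) stop("init must name ",
                                        paste(nm, collapse = ", "))
    list(unlist(init)[nm])
  }
  y <- data$rgr_obs
  sse <- function(ph) sum((y - predict_free(ph, data, fixed, with_enemies))^2)
  best <- NULL; first_error <- NULL
  for (start in starts) {
    run <- if (length(starts) == 1L) {
      fit_one_start(project_free(start, fixed), y, data, fixed,
                    with_enemies, opts, sse, nm, p)
    } else {
      # a start that wanders into a singular configuration just loses
      tryCatch(fit_one_start(project_free(start, fixed), y, data, fixed,
                             with_enemies, opts, sse, nm, p),
               error = function(e) { first_error <<- e; NULL })
    }
    if (is.null(run)) next
    if (is.null(best) || run$obj < best$obj ||
        (run$obj == best$obj && run$converged && !best$converged))
      best <- run
  }
  if (is.null(best)) stop(first_error)
  phi <- best$phi; obj <- best$obj
  converged <- best$converged; iter <- best$iter; msg <- best$msg
  J <- num_jacobian(phi, data, fixed, with_enemies)
  fitted <- predict_free(phi, data, fixed, with_enemies)
  resid <- y - fitted
  xtx <- crossprod(J)
  cov_u <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(cov_u)) {
    warning("singular Jacobian cross-product; correlations unavailable")
    corr <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
    se <- rep(NA_real_, p)
  } else {
    sigma2 <- obj / (n - p)
    corr <- stats::cov2cor(cov_u)
    dimnames(corr) <- list(nm, nm)
    se <- sqrt(pmax(diag(cov_u), 0) * sigma2)
  }
  names(se) <- nm
  params <- rgr_params(s_m = phi[["s_m"]], a = phi[["a"]], b = phi[["b"]],
                       k = phi[["k"]], theta_max = fixed$theta_max,
                       s_max = fixed$s_max, tau = fixed$tau,
                       c_E = if (with_enemies) phi[["c_E"]],
                       c_M = if (with_enemies) phi[["c_M"]])
  structure(list(params = params, estimates = phi, fitted = fitted,
                 residuals = resid, correlation = corr, std_errors = se,
                 convergence = list(converged = converged,
                                    iterations = iter, objective = obj,
                                    method = opts$method, message = msg),
                 n = n, p = p, data = data),
            class = "rgr_fit")
}

#' @export
print.rgr_fit <- function(x, digits = 4, ...) {
  cat("Nonlinear RGR surface fit (", x$convergence$method, "): n = ",
      x$n, ", p = ", x$p, ", SSE = ",
      format(x$convergence$objective, digits = digits),
      if (x$convergence$converged) ", converged in " else
        ", NOT converged after ",
      x$convergence$iterations, " iterations\n", sep = "")
  est <- rbind(estimate = x$estimates, std_error = x$std_errors)
  print(signif(est, digits))
  invisible(x)
}

#' Predicted RGR for a dataset under fitted (or given) parameters
#'
#' @param object an `rgr_fit` or [rgr_params()] object.
#' @param newdata an [build_dataset()]-style data frame (`theta`, `stage`,
#'   and enemy columns when the parameters carry enemy coefficients).
#' @param ... unused.
#' @return Numeric vector of predicted RGR (1/day).
#' @export
predict.rgr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_dataset(object$params, newdata)
}

#' @rdname predict.rgr_fit
#' @param params an [rgr_params()] object.
#' @param data dataset with `theta` and `stage` columns.
#' @export
predict_dataset <- function(params, data) {
  if (!is.null(params$c_E)) {
    if (is.null(data$e_kills) || is.null(data$mummies))
      stop("parameters carry enemy coefficients but data lack enemy counts")
    rgr_with_enemies(data$theta, data$stage, data$e_kills, data$mummies,
                     params)
  } else rgr_surface(data$theta, data$stage, params)
}

#' Asymptotic parameter correlation matrix of a fit
#'
#' Correlations of the free-parameter estimates derived from the inverse
#' cross-product of the final Jacobian, in the reporting order `s_m`,
#' `b`, `k`, `a` (then enemy coefficients).  Requires a converged fit
#' with an invertible cross-product.
#'
#' @param fit an `rgr_fit`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
param_correlations <- function(fit) {
  stopifnot(inherits(fit, "rgr_fit"))
  if (anyNA(fit$correlation))
    stop("singular covariance; correlations unavailable")
  fit$correlation
}
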