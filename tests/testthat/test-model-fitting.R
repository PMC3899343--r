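test_that("weekly mean temperature averages the trailing 7-day window", {
  dates <- as.Date("2001-05-01") + 0:13
  temps <- temperature_series(dates, rep(5, 14),
                              c(rep(12, 7), 10:16), rep(20, 14))
  expect_equal(weekly_mean_temperature(temps, as.Date("2001-05-07")), 12)
  expect_equal(weekly_mean_temperature(temps, as.Date("2001-05-14")), 13)
  # short window: mean of the available days, with a warning
  expect_warning(
    m3 <- weekly_mean_temperature(temps, as.Date("2001-05-03")),
    "fewer than 7")
  expect_equal(m3, 12)
  # no coverage at all: NA
  expect_equal(suppressWarnings(
    weekly_mean_temperature(temps, as.Date("2002-01-01"))), NA_real_)
})

test_that("build_dataset pools fields, drops uncovered dates, sorts stably", {
  st <- default_study(seed = 3, n_fields = 2)
  rgr <- lapply(st$surveys, quiet_estimate)
  ds <- quiet_dataset(st$surveys, rgr, st$weather)
  expect_s3_class(ds, "rgr_dataset")
  expect_equal(nrow(ds), sum(vapply(st$surveys, nrow, 1L)))
  expect_identical(ds, quiet_dataset(rev(st$surveys), rev(rgr),
                                     rev(st$weather)))

  # truncating one weather series drops exactly the uncovered dates
  w_cut <- st$weather
  keep <- w_cut[[1]]$date < max(st$surveys[[1]]$date) - 6
  w_cut[[1]] <- temperature_series(w_cut[[1]]$date[keep],
                                   w_cut[[1]]$t_min[keep],
                                   w_cut[[1]]$t_mean[keep],
                                   w_cut[[1]]$t_max[keep])
  expect_message(
    ds2 <- suppressWarnings(build_dataset(st$surveys, rgr, w_cut)),
    "dropped")
  expect_equal(nrow(ds2), nrow(ds) - 1L)

  expect_error(build_dataset(st$surveys, rgr[1], st$weather), "aligned")
})

test_that("zero-noise regression data is recovered exactly", {
  truth <- c(s_m = 45, b = 1.2, k = 0.35, a = 0.02)
  set.seed(5)
  d <- make_regression_data(160, fix_params(), sigma = 0)
  # init at truth: stays there with ~zero objective
  f <- quiet_fit(d, init = truth)
  expect_true(f$convergence$converged)
  expect_lt(f$convergence$objective, 1e-12)
  expect_equal(f$estimates[names(truth)], truth, tolerance = 1e-6)
  # init perturbed +-20 percent still converges to the truth
  for (fac in c(0.8, 1.2)) {
    fp <- quiet_fit(d, init = truth * fac)
    expect_lt(max(abs(fp$estimates[names(truth)] - truth) / truth), 1e-4)
  }
})

test_that("fit agrees with an independent derivative-free minimizer", {
  set.seed(17)
  d <- make_regression_data(120, fix_params(), sigma = 0.02)
  f <- quiet_fit(d)
  # Nelder-Mead on the same objective from the same default start
  obj <- function(phi) {
    names(phi) <- c("s_m", "b", "k", "a")
    p <- list(s_m = phi[1], b = phi[2], k = phi[3], a = phi[4],
              theta_max = 30, s_max = 92, tau = 2)
    th <- d$theta; s <- d$stage
    live <- th > 0 & th < 30 & s < 92
    pred <- numeric(nrow(d))
    pred[live] <- p$a * th[live]^p$b * (30 - th[live]) / 30 *
      plogis(p$k * (s[live] - p$s_m)) *
      (1 - exp(-(92 - s[live]) / 2))
    sum((d$rgr_obs - pred)^2)
  }
  nm <- stats::optim(f$estimates, obj,
                     control = list(maxit = 5000, reltol = 1e-12))
  # Gauss-Newton found an optimum Nelder-Mead cannot improve materially
  expect_lt(abs(nm$value - f$convergence$objective),
            1e-4 * f$convergence$objective)
})

test_that("objective never increases along accepted Gauss-Newton steps", {
  # monotone objective is implied by step-halving; verify the end state
  # beats the start for several starts
  set.seed(23)
  d <- make_regression_data(100, fix_params(), sigma = 0.05)
  sse0 <- function(phi) sum((d$rgr_obs -
    rgr_surface(d$theta, d$stage,
                rgr_params(s_m = phi[1], a = phi[4], b = phi[2],
                           k = phi[3])))^2)
  for (ini in list(c(s_m = 40, b = 1, k = 0.3, a = 0.02),
                   c(s_m = 60, b = 1.5, k = 0.2, a = 0.01))) {
    f <- quiet_fit(d, init = ini)
    expect_lte(f$convergence$objective, sse0(ini))
  }
})

test_that("fit is invariant to record order", {
  set.seed(31)
  d <- make_regression_data(80, fix_params(), sigma = 0.03)
  f1 <- quiet_fit(d)
  f2 <- quiet_fit(d[sample(nrow(d)), ])
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-8)
})

test_that("Levenberg-Marquardt option reaches the same optimum", {
  set.seed(13)
  d <- make_regression_data(120, fix_params(), sigma = 0.02)
  fgn <- quiet_fit(d)
  flm <- quiet_fit(d, init = c(s_m = 50, b = 1, k = 0.3, a = 0.015),
                   options = list(method = "lm"))
  expect_true(flm$convergence$converged)
  expect_equal(flm$convergence$objective, fgn$convergence$objective,
               tolerance = 1e-4)
})

test_that("asymptotic correlations behave and flag collinearity", {
  set.seed(41)
  d <- make_regression_data(160, fix_params(), sigma = 0.02)
  f <- quiet_fit(d)
  cc <- param_correlations(f)
  expect_equal(rownames(cc), c("s_m", "b", "k", "a"))
  expect_equal(diag(cc), c(s_m = 1, b = 1, k = 1, a = 1))
  expect_true(isSymmetric(cc))
  expect_true(all(cc >= -1 & cc <= 1))
  # power-law scale and exponent are strongly confounded on a narrow
  # thermal window, as in field data
  expect_gt(abs(cc["a", "b"]), 0.9)

  # a deliberately collinear design (single temperature) makes the
  # Jacobian singular in (a, b)
  d2 <- d; d2$theta <- 15
  d2$rgr_obs <- rgr_surface(d2$theta, d2$stage, fix_params())
  expect_error(
    suppressWarnings(fit_rgr_model(d2, init = c(s_m = 45, b = 1.2,
                                                k = 0.35, a = 0.02))),
    "collinear")
})

test_that("enemy coefficients are estimated when requested", {
  set.seed(53)
  d <- make_design(160)
  d$e_kills <- rpois(160, 20)
  d$mummies <- rpois(160, 10)
  pt <- rgr_params(s_m = 45, a = 0.02, b = 1.2, k = 0.35,
                   c_E = -0.002, c_M = -0.001)
  d$rgr_obs <- rgr_with_enemies(d$theta, d$stage, d$e_kills, d$mummies,
                                pt) + rnorm(160, 0, 0.01)
  f <- quiet_fit(d, with_enemies = TRUE)
  expect_equal(unname(f$estimates["c_E"]), -0.002, tolerance = 0.25)
  expect_equal(unname(f$estimates["c_M"]), -0.001, tolerance = 0.5)
  expect_equal(rownames(param_correlations(f)),
               c("s_m", "b", "k", "a", "c_E", "c_M"))
  expect_error(fit_rgr_model(make_regression_data(20, fix_params(), 0.01),
                             with_enemies = TRUE), "e_kills")
})

test_that("truth is covered by +-2 standard errors in most simulations", {
  truth <- c(s_m = 45, b = 1.2, k = 0.35, a = 0.02)
  set.seed(202)
  covered <- vapply(1:100, function(i) {
    d <- make_regression_data(160, fix_params(), sigma = 0.03)
    f <- quiet_fit(d)
    est <- f$estimates[names(truth)]; se <- f$std_errors[names(truth)]
    all(truth >= est - 2 * se & truth <= est + 2 * se)
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("n <= p and bad init are rejected", {
  d <- make_regression_data(4, fix_params(), 0.01)
  expect_error(fit_rgr_model(d), "more records")
  d2 <- make_regression_data(30, fix_params(), 0.01)
  expect_error(fit_rgr_model(d2, init = c(s_m = 45, b = 1.2)), "init")
})
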