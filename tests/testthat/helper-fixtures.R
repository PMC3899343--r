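# shared fixtures, built in code

# canonical surface parameters used throughout the tests
fix_params <- function(a = 0.02)
  rgr_params(s_m = 45, a = a, b = 1.2, k = 0.35)

# a small noiseless weekly survey following n(t) = round(n0 * exp(r t))
exp_survey <- function(r = 0.1, n0 = 5, weeks = 10, tillers = 100) {
  t <- seq(0, weeks * 7, by = 7)
  field_survey(date = as.Date("2001-05-01") + t,
               tillers = tillers,
               aphids = round(n0 * exp(r * t)),
               stage = seq(30, 90, length.out = length(t)),
               field_id = "EXP", region = "test")
}

# confounded (theta, stage) regression design: warm days and advanced
# stages arrive together, as in real seasons
make_design <- function(n) {
  s <- stats::runif(n, 30, 92)
  theta <- pmin(pmax(6 + 12 * (s - 30) / 62 + stats::rnorm(n, 0, 2.5),
                     2), 21.5)
  data.frame(theta = theta, stage = s)
}

# regression data simulated from the surface with gaussian RGR noise
make_regression_data <- function(n, params, sigma) {
  d <- make_design(n)
  d$rgr_obs <- rgr_surface(d$theta, d$stage, params) +
    stats::rnorm(n, 0, sigma)
  d
}

# quiet wrappers: spline boundary and short-window warnings are expected
# on synthetic data and tested separately
quiet_estimate <- function(s) suppressWarnings(estimate_rgr(s))
quiet_dataset <- function(sv, rg, w)
  suppressMessages(suppressWarnings(build_dataset(sv, rg, w)))
quiet_fit <- function(...) suppressWarnings(fit_rgr_model(...))

# default-config study shared across tests
default_study <- function(seed = 1, n_fields = 15)
  suppressWarnings(simulate_fields(sim_config(), n_fields = n_fields,
                                   seed = seed))
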