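#' Simulate a daily temperature series
#'
#' Daily mean temperature is a sinusoidal seasonal curve plus stationary
#' first-order autoregressive anomalies; minimum and maximum are offset
#' symmetrically around the mean by half the diurnal range.  With the
#' default seasonal parameters (annual mean 11 degrees C, amplitude 7.5,
#' peak around day-of-year 200) the curve mimics a temperate western
#' European wheat-growing season, and the generated daily means are capped
#' at `t_mean_cap` (22 degrees C by default) so that no spring/summer mean
#' daily temperature exceeds the warmest means seen in such climates.
#'
#' @param start_date first day (`Date` or ISO-8601 string).
#' @param n_days number of days (>= 1).
#' @param seasonal list with `mean` (annual mean, degrees C), `amplitude`
#'   (seasonal half-range) and `peak_doy` (day of year of the warmest day).
#' @param noise list with `sd` (marginal standard deviation of the daily
#'   anomaly, degrees C) and `ar` (lag-1 autocorrelation, in `[0, 1)`).
#' @param t_mean_cap upper cap applied to the daily mean (degrees C);
#'   `Inf` disables it.
#' @param diurnal_half_range half of the min-to-max daily spread.
#' @param seed optional integer; fixing it makes the output reproducible
#'   bit for bit.
#' @return A [temperature_series()].
#' @examples
#' w <- gen_temperature("2001-05-01", 76, seed = 1)
#' max(w$t_mean)   # never above 22
#' @export
gen_temperature <- function(start_date, n_days,
                            seasonal = list(mean = 11, amplitude = 7.5,
                                            peak_doy = 200),
                            noise = list(sd = 1.5, ar = 0.6),
                            t_mean_cap = 22, diurnal_half_range = 5,
                            seed = NULL) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (noise$ar < 0 || noise$ar >= 1)
    stop("noise autocorrelation must be in [0, 1)")
  if (noise$sd < 0) stop("noise sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(strftime(dates, "%j"))
  seas <- seasonal$mean +
    seasonal$amplitude * cos(2 * pi * (doy - seasonal$peak_doy) / 365)
  eps <- numeric(n_days)
  if (noise$sd > 0) {
    eps[1] <- stats::rnorm(1, 0, noise$sd)
    innov_sd <- noise$sd * sqrt(1 - noise$ar^2)
    if (n_days > 1)
      for (i in 2:n_days)
        eps[i] <- noise$ar * eps[i - 1] + stats::rnorm(1, 0, innov_sd)
  }
  t_mean <- pmin(seas + eps, t_mean_cap)
  temperature_series(dates,
                     t_min = t_mean - diurnal_half_range,
                     t_mean = t_mean,
                     t_max = t_mean + diurnal_half_range)
}

#' Simulate wheat phenology by degree-day accumulation
#'
#' Zadoks stage advances proportionally to thermal time: each day
#' contributes `max(0, t_mean - base_temp)` degree-days and the stage
#' rises by that amount divided by `degree_days_per_stage`, capped at 99.
#' Driving phenology with the same temperatures that drive aphid growth
#' reproduces the diagonal confounding of temperature and crop stage that
#' characterises real field seasons (warm days and advanced stages arrive
#' together).  The default of 20.2 degree-days per Zadoks unit is
#' calibrated so that a season started at stage 30 on 1 May under the
#' default seasonal temperature curve reaches grain ripening (stage
#' 91--92) by mid-July.
#'
#' @param temps a [temperature_series()].
#' @param base_temp development threshold (degrees C), default 0.
#' @param degree_days_per_stage thermal time per Zadoks unit (> 0).
#' @param start_stage stage on the first day, in `[0, 99)`.
#' @return A [phenology_track()] on the same dates as `temps`.
#' @export
gen_phenology <- function(temps, base_temp = 0, degree_days_per_stage = 20.2,
                          start_stage = 30) {
  stopifnot(inherits(temps, "temperature_series"))
  if (nrow(temps) == 0L) stop("empty temperature series")
  if (degree_days_per_stage <= 0) stop("degree_days_per_stage must be > 0")
  if (start_stage < 0 || start_stage >= 99)
    stop("start_stage must be in [0, 99)")
  dd <- pmax(0, temps$t_mean - base_temp)
  stage <- pmin(start_stage + cumsum(dd) / degree_days_per_stage, 99)
  phenology_track(temps$date, stage)
}

#' Integrate the latent aphid density trajectory
#'
#' Daily Euler integration of per-tiller aphid density under the RGR
#' surface: `N[t+1] = N[t] * (1 + f(theta[t], s[t]))` with a 1-day step,
#' starting from `n0`.  At weekly observation spacing the first-order
#' integration error is negligible compared with sampling noise.
#' Immigration and emigration are not modelled separately; they are part
#' of what the RGR surface absorbs.
#'
#' @param true_params an [rgr_params()] generating the dynamics.
#' @param temps a [temperature_series()].
#' @param phen a [phenology_track()] on exactly the same dates.
#' @param n0 initial density (aphids per tiller, > 0).
#' @return Data frame with columns `date` and `density` (> 0 throughout).
#' @examples
#' # constant growth r gives the Euler closed form n0 * (1 + r)^t
#' @export
gen_population <- function(true_params, temps, phen, n0 = 0.05) {
  stopifnot(inherits(temps, "temperature_series"),
            inherits(phen, "phenology_track"))
  if (n0 <= 0) stop("n0 must be > 0")
  if (nrow(temps) != nrow(phen) || any(temps$date != phen$date))
    stop("temperature and phenology dates do not match")
  f <- rgr_surface(temps$t_mean, phen$stage, true_params)
  n <- nrow(temps)
  dens <- numeric(n)
  dens[1] <- n0
  if (n > 1)
    for (i in 2:n) dens[i] <- dens[i - 1] * max(1 + f[i - 1], 1e-12)
  data.frame(date = temps$date, density = dens)
}

#' Draw an observed field survey from a latent trajectory
#'
#' Observation model for weekly sampling: the total aphid count over the
#' inspected tillers is negative-binomially distributed with mean
#' `density * tillers` and dispersion parameter `overdispersion` (the
#' `size` of [stats::rnbinom()]; variance `mu + mu^2/size`, so
#' `size = Inf` is the Poisson limit).  Optional enemy counts (`e_kills`,
#' `mummies`) are drawn the same way with means proportional to the aphid
#' mean through `enemy_rates`.
#'
#' @param latent data frame from [gen_population()].
#' @param temps,phen the series the trajectory was generated from.
#' @param weekly_dates sampling dates; must be a subset of `latent$date`.
#' @param tillers tillers inspected per date (scalar or vector, 50--1000).
#' @param overdispersion negative-binomial size parameter (> 0 or `Inf`).
#' @param enemy_rates length-2 non-negative proportionality constants for
#'   `e_kills` and `mummies`, or `NULL` to omit enemy columns.
#' @param field_id,region labels for the resulting survey.
#' @param seed optional integer seed.
#' @return A [field_survey()].
#' @export
gen_survey <- function(latent, temps, phen, weekly_dates, tillers = 200,
                       overdispersion = 5, enemy_rates = NULL,
                       field_id = "field1", region = "synthetic",
                       seed = NULL) {
  stopifnot(inherits(phen, "phenology_track"))
  if (!all(weekly_dates %in% latent$date))
    stop("weekly date outside the simulated range")
  if (any(tillers < 50 | tillers > 1000))
    stop("tillers outside [50, 1000]")
  if (overdispersion <= 0) stop("overdispersion must be > 0")
  if (!is.null(seed)) set.seed(seed)
  weekly_dates <- as.Date(weekly_dates)
  idx <- match(weekly_dates, latent$date)
  tillers <- rep_len(tillers, length(idx))
  mu <- latent$density[idx] * tillers
  aphids <- rnbinom_mu(length(mu), mu, overdispersion)
  stage <- phen$stage[match(weekly_dates, phen$date)]
  e_kills <- mummies <- NULL
  if (!is.null(enemy_rates)) {
    if (length(enemy_rates) != 2L || any(enemy_rates < 0))
      stop("enemy_rates must be two non-negative numbers")
    e_kills <- rnbinom_mu(length(mu), enemy_rates[1] * mu, overdispersion)
    mummies <- rnbinom_mu(length(mu), enemy_rates[2] * mu, overdispersion)
  }
  field_survey(weekly_dates, tillers, aphids, stage,
               e_kills = e_kills, mummies = mummies,
               field_id = field_id, region = region)
}

# NB draw parameterized by mean; size = Inf falls back to Poisson,
# zero means give zero counts exactly
rnbinom_mu <- function(n, mu, size) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (is.infinite(size)) stats::rpois(sum(pos), mu[pos])
                else stats::rnbinom(sum(pos), mu = mu[pos], size = size)
  }
  out
}

#' Simulation configuration
#'
#' Bundles everything [simulate_fields()] needs for one synthetic study:
#' the true RGR surface, the observation-noise level, sampling effort and
#' the weather/phenology settings.  Defaults describe a typical temperate
#' season: sampling starts 1 May at stem extension (stage 30) and runs
#' weekly until 15 July, populations start at 0.05 aphids per tiller and
#' peak around 20--30 (an outbreak year), 200 tillers are inspected per
#' sample, and counts are negative-binomial with dispersion 10 -- a noise
#' level under which the fitted surface explains roughly a quarter to a
#' half of the RGR variance, as regional field datasets do.
#'
#' @param true_params [rgr_params()] driving the latent dynamics.
#' @param n0 initial aphid density per tiller (> 0).
#' @param overdispersion negative-binomial size of the count noise (> 0).
#' @param enemy_rates length-2 non-negative rates for enemy counts, or
#'   `NULL` for surveys without enemy records.
#' @param tillers tillers inspected per sampling date.
#' @param base_temp,degree_days_per_stage,start_stage see [gen_phenology()].
#' @param start_date season start (1 May by default).
#' @param n_days season length in days (76 reaches 15 July).
#' @param sampling_interval days between samples (7 = weekly).
#' @param seasonal,noise,t_mean_cap see [gen_temperature()].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(true_params = rgr_params(s_m = 45, a = 0.01,
                                                b = 1.2, k = 0.35),
                       n0 = 0.05, overdispersion = 10,
                       enemy_rates = NULL, tillers = 200,
                       base_temp = 0, degree_days_per_stage = 20.2,
                       start_stage = 30,
                       start_date = "2001-05-01", n_days = 76,
                       sampling_interval = 7,
                       seasonal = list(mean = 11, amplitude = 7.5,
                                       peak_doy = 200),
                       noise = list(sd = 1.5, ar = 0.6),
                       t_mean_cap = 22) {
  if (n0 <= 0) stop("n0 must be > 0")
  if (overdispersion <= 0) stop("overdispersion must be > 0")
  structure(list(true_params = true_params, n0 = n0,
                 overdispersion = overdispersion,
                 enemy_rates = enemy_rates, tillers = tillers,
                 base_temp = base_temp,
                 degree_days_per_stage = degree_days_per_stage,
                 start_stage = start_stage, start_date = start_date,
                 n_days = n_days, sampling_interval = sampling_interval,
                 seasonal = seasonal, noise = noise,
                 t_mean_cap = t_mean_cap),
            class = "sim_config")
}

#' Simulate a multi-field synthetic study
#'
#' Generates `n_fields` independent field-years under one [sim_config()]:
#' per field a weather realisation, the induced phenology, the latent
#' density trajectory and an observed weekly [field_survey()].  Field
#' seasons are labelled with consecutive years so that surveys can be
#' pooled the way multi-year regional datasets are.
#'
#' @param config a [sim_config()].
#' @param n_fields number of field-years.
#' @param seed integer seed controlling all randomness.
#' @param region region label for the surveys.
#' @return A list of class `"sim_study"` with elements `surveys`,
#'   `weather`, `phenology` and `latent` (parallel lists, one entry per
#'   field), plus the `config` and `seed` used.
#' @export
simulate_fields <- function(config = sim_config(), n_fields = 15, seed = 1,
                            region = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_fields)
  start <- as.Date(config$start_date)
  year0 <- as.integer(strftime(start, "%Y"))
  surveys <- weather <- phenology <- latent <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    st <- as.Date(strftime(start, format = paste0(year0 + i - 1L, "-%m-%d")))
    w <- gen_temperature(st, config$n_days, seasonal = config$seasonal,
                         noise = config$noise,
                         t_mean_cap = config$t_mean_cap,
                         seed = sub_seeds[2L * i - 1L])
    ph <- gen_phenology(w, base_temp = config$base_temp,
                        degree_days_per_stage = config$degree_days_per_stage,
                        start_stage = config$start_stage)
    traj <- gen_population(config$true_params, w, ph, n0 = config$n0)
    wk <- seq(st, st + config$n_days - 1L, by = config$sampling_interval)
    sv <- gen_survey(traj, w, ph, wk, tillers = config$tillers,
                     overdispersion = config$overdispersion,
                     enemy_rates = config$enemy_rates,
                     field_id = sprintf("F%02d", i), region = region,
                     seed = sub_seeds[2L * i])
    surveys[[i]] <- sv; weather[[i]] <- w
    phenology[[i]] <- ph; latent[[i]] <- traj
  }
  structure(list(surveys = surveys, weather = weather,
                 phenology = phenology, latent = latent,
                 config = config, seed = seed),
            class = "sim_study")
}
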