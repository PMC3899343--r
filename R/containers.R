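#' Daily temperature series
#'
#' A validated daily weather record: one row per calendar day with minimum,
#' mean and maximum air temperature (degrees Celsius, standard 2 m shelter
#' measurements).  Weekly means of `t_mean` are the temperature covariate
#' of the RGR response surface (see [weekly_mean_temperature()]).
#'
#' @param date `Date` vector, strictly increasing.
#' @param t_min,t_mean,t_max numeric, one value per day, with
#'   `t_min <= t_mean <= t_max` on every day.
#' @return A data frame of class `"temperature_series"` with columns
#'   `date`, `t_min`, `t_mean`, `t_max`.
#' @details Gaps (missing calendar days inside the range) are tolerated but
#'   flagged with a warning: downstream weekly aggregation averages the
#'   days that are present.
#' @seealso [gen_temperature()], [read_weather_csv()]
#' @export
temperature_series <- function(date, t_min, t_mean, t_max) {
  date <- as.Date(date)
  n <- length(date)
  if (n == 0L) stop("empty temperature series")
  if (length(t_min) != n || length(t_mean) != n || length(t_max) != n)
    stop("temperature columns must all have length ", n)
  if (anyNA(date)) stop("unparseable date in temperature series")
  if (n > 1L && any(diff(as.numeric(date)) <= 0))
    stop("dates must be strictly increasing")
  bad <- which(t_min > t_mean | t_mean > t_max)
  if (length(bad))
    stop("t_min <= t_mean <= t_max violated at row(s) ",
         paste(bad, collapse = ", "))
  if (n > 1L && any(diff(as.numeric(date)) > 1))
    warning(sum(diff(as.numeric(date)) > 1), " gap(s) in daily coverage")
  structure(
    data.frame(date = date, t_min = t_min, t_mean = t_mean, t_max = t_max),
    class = c("temperature_series", "data.frame"))
}

#' Wheat phenology track
#'
#' Zadoks decimal growth-stage codes (0--99) over calendar time; stages must
#' be non-decreasing (a crop never reverts to an earlier stage).
#'
#' @param date `Date` vector, strictly increasing.
#' @param stage numeric Zadoks codes in `[0, 99]`, non-decreasing.
#' @return A data frame of class `"phenology_track"`.
#' @seealso [gen_phenology()]
#' @export
phenology_track <- function(date, stage) {
  date <- as.Date(date)
  if (length(date) != length(stage)) stop("date and stage lengths differ")
  if (length(date) == 0L) stop("empty phenology track")
  if (any(stage < 0 | stage > 99)) stop("Zadoks stage outside [0, 99]")
  if (length(stage) > 1L && any(diff(stage) < 0))
    stop("stage must be non-decreasing; violated at row(s) ",
         paste(which(diff(stage) < 0) + 1L, collapse = ", "))
  if (length(date) > 1L && any(diff(as.numeric(date)) <= 0))
    stop("dates must be strictly increasing")
  structure(data.frame(date = date, stage = stage),
            class = c("phenology_track", "data.frame"))
}

#' Weekly field survey of a single field-year
#'
#' One field-year of weekly aphid counts on winter wheat: at each sampling
#' date a number of tillers (50--1000, depending on infestation) is
#' inspected and the living aphids on them are counted, together with the
#' Zadoks growth stage of the crop.  Optionally the survey also records
#' natural-enemy evidence: aphid cadavers killed by entomopathogenic fungi
#' (`e_kills`) and parasitoid mummies (`mummies`); these two columns are
#' either both present or both absent.
#'
#' @param date `Date` vector of sampling dates, strictly increasing,
#'   approximately weekly.
#' @param tillers integer, tillers inspected per date, in `[50, 1000]`.
#' @param aphids integer, total living aphids counted over the inspected
#'   tillers (non-negative).
#' @param stage Zadoks stage per date, non-decreasing, in `[0, 99]`.
#' @param e_kills,mummies optional non-negative integer counts of
#'   fungus-killed aphids and parasitoid mummies in the same sample.
#' @param field_id,region labels identifying the field-year and region.
#' @return A data frame of class `"field_survey"` with attributes
#'   `field_id` and `region`; column `density` (aphids per tiller) is
#'   derived and attached for convenience.
#' @seealso [gen_survey()], [estimate_rgr()], [read_survey_csv()]
#' @export
field_survey <- function(date, tillers, aphids, stage,
                         e_kills = NULL, mummies = NULL,
                         field_id = "field1", region = "synthetic") {
  date <- as.Date(date)
  n <- length(date)
  if (n == 0L) stop("empty survey")
  if (anyNA(date)) stop("unparseable sampling date")
  if (n > 1L && any(diff(as.numeric(date)) <= 0))
    stop("sampling dates must be strictly increasing; violated at row(s) ",
         paste(which(diff(as.numeric(date)) <= 0) + 1L, collapse = ", "))
  chk_len <- function(x, nm)
    if (length(x) != n) stop(nm, " must have length ", n)
  if (length(tillers) == 1L) tillers <- rep(tillers, n)
  chk_len(tillers, "tillers"); chk_len(aphids, "aphids"); chk_len(stage, "stage")
  bad <- which(tillers < 50 | tillers > 1000)
  if (length(bad))
    stop("tillers outside [50, 1000] at row(s) ", paste(bad, collapse = ", "))
  bad <- which(aphids < 0)
  if (length(bad))
    stop("negative aphid count at row(s) ", paste(bad, collapse = ", "))
  if (any(stage < 0 | stage > 99)) stop("Zadoks stage outside [0, 99]")
  if (n > 1L && any(diff(stage) < 0))
    stop("stage must be non-decreasing; violated at row(s) ",
         paste(which(diff(stage) < 0) + 1L, collapse = ", "))
  if (is.null(e_kills) != is.null(mummies))
    stop("e_kills and mummies must be both present or both absent")
  df <- data.frame(date = date, tillers = as.integer(tillers),
                   aphids = as.integer(aphids), stage = stage,
                   density = aphids / tillers)
  if (!is.null(e_kills)) {
    chk_len(e_kills, "e_kills"); chk_len(mummies, "mummies")
    bad <- which(e_kills < 0 | mummies < 0)
    if (length(bad))
      stop("negative enemy count at row(s) ", paste(bad, collapse = ", "))
    df$e_kills <- as.integer(e_kills)
    df$mummies <- as.integer(mummies)
  }
  structure(df, field_id = as.character(field_id),
            region = as.character(region),
            class = c("field_survey", "data.frame"))
}

#' @export
print.field_survey <- function(x, ...) {
  cat("Field survey ", attr(x, "field_id"), " (", attr(x, "region"), "): ",
      nrow(x), " weekly samples, stages ",
      format(min(x$stage)), "-", format(max(x$stage)),
      if (!is.null(x$e_kills)) ", with enemy counts" else "", "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Does a survey have natural-enemy columns?
#' @param survey a [field_survey()].
#' @return `TRUE` if `e_kills`/`mummies` are recorded.
#' @export
has_enemies <- function(survey) {
  !is.null(survey$e_kills) && !is.null(survey$mummies)
}
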