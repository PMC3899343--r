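# All files are comma-separated UTF-8 with '.' decimals, a mandatory
# header row, ISO-8601 dates, and a leading '#' metadata comment carrying
# the package version, the seed and a config fingerprint when known.

meta_header <- function(seed = NULL, config = NULL) {
  paste0("# aphidRGR ",
         as.character(utils::packageVersion("aphidRGR")),
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(config)) paste0(" config=", config_hash(config)))
}

#' Fingerprint of a configuration object
#'
#' Deterministic 31-bit polynomial hash of the deparsed configuration,
#' recorded in output-file headers so artifacts can be traced to the
#' settings that produced them.
#'
#' @param config any serializable R object.
#' @return Integer-valued hash as a character string.
#' @export
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  sprintf("%d", h)
}

write_csv_meta <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write field-survey CSV files
#'
#' Survey files have mandatory columns `field_id`, `region`, `date`
#' (ISO-8601), `tillers`, `aphids`, `stage` and optional `e_kills`,
#' `mummies` (both or neither).  A file may hold several field-years;
#' each is validated through [field_survey()] (tiller range, strictly
#' increasing dates, monotone stages, non-negative counts) and rejected
#' with a row-numbered message on violation.  Writing then reading a
#' survey reproduces it exactly.
#'
#' @param path file path.
#' @return `read_survey_csv()`: a single [field_survey()] when the file
#'   holds one field, otherwise a named list of them.
#' @export
read_survey_csv <- function(path) {
  df <- read_csv_meta(path)
  need <- c("field_id", "region", "date", "tillers", "aphids", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$e_kills) != is.null(df$mummies))
    stop("e_kills and mummies must be both present or both absent")
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable date at row(s) ",
         paste(which(is.na(dates)), collapse = ", "))
  df$date <- dates
  out <- lapply(split(df, df$field_id), function(d) {
    field_survey(d$date, d$tillers, d$aphids, d$stage,
                 e_kills = d$e_kills, mummies = d$mummies,
                 field_id = d$field_id[1], region = d$region[1])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_survey_csv
#' @param survey a [field_survey()] or a list of them.
#' @param seed,config optional provenance recorded in the file header.
#' @export
write_survey_csv <- function(survey, path, seed = NULL, config = NULL) {
  if (inherits(survey, "field_survey")) survey <- list(survey)
  rows <- lapply(survey, function(s) {
    d <- as.data.frame(s)
    d$density <- NULL
    cbind(field_id = attr(s, "field_id"), region = attr(s, "region"), d)
  })
  write_csv_meta(do.call(rbind, rows), path, seed = seed, config = config)
  invisible(path)
}

#' Read and write daily weather CSV files
#'
#' Weather files have columns `date`, `t_min`, `t_mean`, `t_max` and may
#' carry an optional `field_id` column when one file stores the station
#' records of several field-years.  Rows with `t_min > t_max` are
#' rejected with their row index; gaps in daily coverage are accepted
#' with a warning.
#'
#' @param path file path.
#' @return A single [temperature_series()] or a named list of them.
#' @export
read_weather_csv <- function(path) {
  df <- read_csv_meta(path)
  need <- c("date", "t_min", "t_mean", "t_max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$t_min > df$t_max)
  if (length(bad))
    stop("t_min > t_max at row(s) ", paste(bad, collapse = ", "))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable date at row(s) ",
         paste(which(is.na(dates)), collapse = ", "))
  df$date <- dates
  if (is.null(df$field_id))
    return(temperature_series(df$date, df$t_min, df$t_mean, df$t_max))
  out <- lapply(split(df, df$field_id), function(d)
    temperature_series(d$date, d$t_min, d$t_mean, d$t_max))
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_weather_csv
#' @param temps a [temperature_series()] or a (possibly named) list.
#' @param seed,config optional provenance recorded in the file header.
#' @export
write_weather_csv <- function(temps, path, seed = NULL, config = NULL) {
  if (inherits(temps, "temperature_series")) {
    df <- as.data.frame(temps)
  } else {
    ids <- names(temps)
    if (is.null(ids)) ids <- sprintf("F%02d", seq_along(temps))
    df <- do.call(rbind, Map(function(t, id)
      cbind(field_id = id, as.data.frame(t)), temps, ids))
  }
  write_csv_meta(df, path, seed = seed, config = config)
  invisible(path)
}

#' Write estimated RGR series to CSV
#'
#' Columns `field_id`, `date`, `rgr`, `log_count`, `smoothing_parameter`.
#'
#' @param rgr an `rgr_series` or a list of them.
#' @param path file path.
#' @param seed,config optional provenance recorded in the file header.
#' @export
write_rgr_csv <- function(rgr, path, seed = NULL, config = NULL) {
  if (inherits(rgr, "rgr_series")) rgr <- list(rgr)
  df <- do.call(rbind, lapply(rgr, function(r)
    data.frame(field_id = attr(r, "field_id"), date = r$date,
               rgr = r$rgr, log_count = r$log_count,
               smoothing_parameter = attr(r, "smoothing_parameter"))))
  write_csv_meta(df, path, seed = seed, config = config)
  invisible(path)
}

#' Write a prediction grid to CSV
#'
#' Matrix layout with coordinate headers: first column the temperature
#' coordinate, remaining columns one per stage value.
#'
#' @param grid a [prediction_grid()] result.
#' @param path file path.
#' @param seed,config optional provenance recorded in the file header.
#' @export
write_grid_csv <- function(grid, path, seed = NULL, config = NULL) {
  stopifnot(inherits(grid, "rgr_grid"))
  df <- data.frame(theta = grid$theta, grid$rgr, check.names = FALSE)
  names(df) <- c("theta", paste0("s", signif(grid$stage, 6)))
  write_csv_meta(df, path, seed = seed, config = config)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (decided by extension), merged over the package
#' defaults.  Recognised top-level keys: `seed`, `n_fields`, `fixed`
#' (`theta_max`, `s_max`, `tau`), `fit` (`with_enemies`, `method`,
#' `max_iter`, `tol`), and `sim` (any argument of [sim_config()];
#' `true_params` given as a flat list of [rgr_params()] values).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   pure defaults.
#' @return A list of class `"pipeline_config"` with elements `seed`,
#'   `n_fields`, `fixed`, `fit` and `sim` (a [sim_config()]).
#' @export
read_config <- function(path = NULL) {
  defaults <- list(seed = 1L, n_fields = 15L,
                   fixed = list(theta_max = 30, s_max = 92, tau = 2),
                   fit = list(with_enemies = FALSE, method = "gn",
                              max_iter = 200L, tol = 1e-8),
                   sim = list())
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(user)) stop("invalid config file: ", path)
  }
  cfg <- utils::modifyList(defaults, user)
  sim_args <- cfg$sim
  if (!is.null(sim_args$true_params) && !inherits(sim_args$true_params,
                                                  "rgr_params"))
    sim_args$true_params <- params_from_list(as.list(sim_args$true_params))
  if (!is.null(sim_args$enemy_rates))
    sim_args$enemy_rates <- as.numeric(sim_args$enemy_rates)
  cfg$sim <- do.call(sim_config, sim_args)
  structure(cfg, class = "pipeline_config")
}
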