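# CSV readers/writers for the three input streams. Dialect: comma-separated,
# UTF-8, header required, decimal point only (no locale-dependent parsing).

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.canonical_direction <- function(x, what = "screening data") {
  up <- toupper(trimws(as.character(x)))
  bad <- !(up %in% SECTORS)
  if (any(bad))
    stop(sprintf("%s: unknown direction token(s): %s (expected one of %s)",
                 what, paste(unique(x[bad]), collapse = ", "),
                 paste(SECTORS, collapse = ", ")), call. = FALSE)
  up
}

#' Read (or validate) screening records
#'
#' A screening record is one (year, direction, distance) cell: the number of
#' receptor seedlings sprayed with the discriminating herbicide rate and the
#' number surviving (carrying the resistance trait). Distances are measured
#' from the edge of the pollen-donor block.
#'
#' @param path CSV file with header columns `year`, `direction`,
#'   `distance_m`, `n_screened`, `n_resistant`.
#' @return data.frame of validated records, row order preserved, with class
#'   `c("screening_records", "data.frame")`. Direction tokens are stored
#'   uppercase (parsing is case-insensitive).
#' @seealso [write_screening()], [generate_screening()]
#' @export
read_screening <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(year = "character"))
  as_screening_records(df)
}

#' @rdname read_screening
#' @param df a data.frame with the screening columns (e.g. constructed in
#'   code rather than read from disk).
#' @export
as_screening_records <- function(df) {
  .require_columns(df, c("year", "direction", "distance_m", "n_screened",
                         "n_resistant"), "screening data")
  df$year <- as.character(df$year)
  df$direction <- .canonical_direction(df$direction)
  df$distance_m <- as.numeric(df$distance_m)
  df$n_screened <- as.integer(df$n_screened)
  df$n_resistant <- as.integer(df$n_resistant)
  if (any(!is.finite(df$distance_m)) || any(df$distance_m <= 0))
    stop("screening data: distance_m must be finite and > 0", call. = FALSE)
  if (any(df$n_screened < 0) || any(df$n_resistant < 0))
    stop("screening data: counts must be non-negative", call. = FALSE)
  bad <- which(df$n_resistant > df$n_screened)
  if (length(bad))
    stop(sprintf("screening data: n_resistant > n_screened at row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  class(df) <- c("screening_records", "data.frame")
  df
}

#' @rdname read_screening
#' @param x screening records to write.
#' @export
write_screening <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(
    x[, c("year", "direction", "distance_m", "n_screened", "n_resistant")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read hourly weather records
#'
#' Expects the six logger columns `timestamp` (ISO-8601, hourly),
#' `air_temp_c`, `precip_mm`, `rh_pct`, `wind_speed_ms`, `wind_dir_deg`.
#' Wind direction follows the meteorological convention: the bearing the
#' wind blows FROM, degrees in \[0, 360). The stream is returned sorted
#' chronologically; gaps (missing hours) are tolerated -- field loggers drop
#' records -- and reported via `message()`, and all downstream aggregations
#' divide by observed hours, never nominal hours.
#'
#' @param path CSV file path.
#' @return data.frame of class `c("weather_records", "data.frame")` with a
#'   POSIXct `timestamp` column (UTC).
#' @export
read_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("weather file is empty; returning an empty stream", call. = FALSE)
    df <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                     air_temp_c = numeric(), precip_mm = numeric(),
                     rh_pct = numeric(), wind_speed_ms = numeric(),
                     wind_dir_deg = numeric())
    class(df) <- c("weather_records", "data.frame")
    return(df)
  }
  as_weather_records(df)
}

#' @rdname read_weather
#' @param df a data.frame with the six weather columns.
#' @export
as_weather_records <- function(df) {
  .require_columns(df, c("timestamp", "air_temp_c", "precip_mm", "rh_pct",
                         "wind_speed_ms", "wind_dir_deg"), "weather data")
  ts <- df$timestamp
  if (!inherits(ts, "POSIXct")) {
    parsed <- as.POSIXct(as.character(ts), tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                        "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
    bad <- which(is.na(parsed) & !is.na(ts))
    if (length(bad))
      stop(sprintf("weather data: unparseable timestamp at line(s) %s",
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    df$timestamp <- parsed
  }
  for (col in c("air_temp_c", "precip_mm", "rh_pct", "wind_speed_ms",
                "wind_dir_deg"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$wind_speed_ms < 0, na.rm = TRUE))
    stop("weather data: negative wind speed", call. = FALSE)
  if (any(df$wind_dir_deg < 0 | df$wind_dir_deg >= 360, na.rm = TRUE))
    stop("weather data: wind_dir_deg must lie in [0, 360)", call. = FALSE)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1) {
    gaps <- sum(as.numeric(diff(df$timestamp), units = "hours") > 1.5)
    if (gaps > 0)
      message(sprintf("weather stream: %d gap(s) of more than one hour", gaps))
  }
  class(df) <- c("weather_records", "data.frame")
  df
}

#' @rdname read_weather
#' @param x weather records to write.
#' @export
write_weather <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x[, c("timestamp", "air_temp_c", "precip_mm", "rh_pct",
               "wind_speed_ms", "wind_dir_deg")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read flowering observations
#'
#' Observations at a roughly 5-day cadence of the percentage of plants
#' flowering at each block. The donor block additionally records the
#' percentage of plants shedding pollen (`pct_shedding`); receptor rows
#' leave it `NA`. Receptor blocks are identified by `direction` and
#' `distance_m`; the donor row has `block_type = "donor"` and `NA` for both.
#'
#' @param path CSV with columns `date`, `block_type` (`donor`/`receptor`),
#'   `direction`, `distance_m`, `pct_flowering`, `pct_shedding`.
#' @return data.frame of class `c("flowering_records", "data.frame")`.
#' @export
read_flowering <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_flowering_records(df)
}

#' @rdname read_flowering
#' @param df a data.frame with the flowering columns.
#' @export
as_flowering_records <- function(df) {
  .require_columns(df, c("date", "block_type", "direction", "distance_m",
                         "pct_flowering", "pct_shedding"), "flowering data")
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stop("flowering data: unparseable date",
                                call. = FALSE)
  df$block_type <- match.arg(tolower(as.character(df$block_type)),
                             c("donor", "receptor"), several.ok = TRUE)
  rec <- df$block_type == "receptor"
  if (any(rec)) df$direction[rec] <- .canonical_direction(df$direction[rec],
                                                          "flowering data")
  df$distance_m <- as.numeric(df$distance_m)
  for (col in c("pct_flowering", "pct_shedding")) {
    v <- as.numeric(df[[col]])
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop(sprintf("flowering data: %s outside [0, 100]", col), call. = FALSE)
    df[[col]] <- v
  }
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("flowering_records", "data.frame")
  df
}

#' @rdname read_flowering
#' @param x flowering records to write.
#' @export
write_flowering <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x[, c("date", "block_type", "direction", "distance_m",
               "pct_flowering", "pct_shedding")]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
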