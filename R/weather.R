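#' Construct a daily weather series
#'
#' A weather series is a data frame of contiguous daily records with the
#' columns `date` (class `Date`), `tmin_c`, `tmax_c` (daily temperature
#' extremes, degrees C), `radiation_mj_m2` (global solar radiation,
#' MJ m-2 d-1) and `rain_mm` (precipitation, mm d-1), carrying the site
#' latitude as an attribute. The constructor validates the physical
#' invariants (tmin <= tmax, non-negative radiation and rain) and that
#' dates are strictly consecutive calendar days.
#'
#' @param data data frame with columns `date`, `tmin_c`, `tmax_c`,
#'   `radiation_mj_m2`, `rain_mm`.
#' @param latitude site latitude in degrees north, in \[-90, 90\].
#' @return A `weather_series` object (a validated data frame with a
#'   `latitude` attribute).
#' @export
weather_series <- function(data, latitude) {
  required <- c("date", "tmin_c", "tmax_c", "radiation_mj_m2", "rain_mm")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("weather data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) {
    stop("weather data is empty: at least one daily record is required",
         call. = FALSE)
  }
  if (!is.numeric(latitude) || length(latitude) != 1L || is.na(latitude) ||
      latitude < -90 || latitude > 90) {
    stop("latitude must be a single number in [-90, 90]", call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  if (!inherits(data$date, "Date")) {
    parsed <- as.Date(as.character(data$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) {
      stop("unparseable ISO-8601 date in row ", bad[1L], ": '",
           data$date[bad[1L]], "'", call. = FALSE)
    }
    data$date <- parsed
  }
  dup <- which(duplicated(data$date))
  if (length(dup) > 0L) {
    stop("duplicated date in row ", dup[1L], ": ", data$date[dup[1L]],
         call. = FALSE)
  }
  if (is.unsorted(data$date)) {
    stop("weather dates are not in increasing order", call. = FALSE)
  }
  gaps <- which(diff(as.integer(data$date)) > 1L)
  if (length(gaps) > 0L) {
    stop("non-consecutive weather dates: gap at ",
         format(data$date[gaps[1L]] + 1L), " (after row ", gaps[1L], ")",
         call. = FALSE)
  }
  for (col in c("tmin_c", "tmax_c", "radiation_mj_m2", "rain_mm")) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad) > 0L) {
      stop("non-finite ", col, " in row ", bad[1L], " (",
           format(data$date[bad[1L]]), ")", call. = FALSE)
    }
  }
  bad <- which(data$tmin_c > data$tmax_c)
  if (length(bad) > 0L) {
    stop("tmin_c > tmax_c in row ", bad[1L], " (",
         format(data$date[bad[1L]]), ")", call. = FALSE)
  }
  bad <- which(data$radiation_mj_m2 < 0)
  if (length(bad) > 0L) {
    stop("negative radiation_mj_m2 in row ", bad[1L], " (",
         format(data$date[bad[1L]]), ")", call. = FALSE)
  }
  bad <- which(data$rain_mm < 0)
  if (length(bad) > 0L) {
    stop("negative rain_mm in row ", bad[1L], " (",
         format(data$date[bad[1L]]), ")", call. = FALSE)
  }
  rownames(data) <- NULL
  attr(data, "latitude") <- latitude
  class(data) <- c("weather_series", "data.frame")
  data
}

#' Read a daily weather series from CSV
#'
#' The file must have the exact header
#' `date,tmin_c,tmax_c,radiation_mj_m2,rain_mm` with ISO-8601 dates.
#' All `weather_series` invariants are enforced; a validation failure
#' names the offending row.
#'
#' @param source path to a CSV file (or a connection).
#' @param latitude site latitude in degrees north.
#' @return A [weather_series()].
#' @export
read_weather <- function(source, latitude = 51.8) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) {
    stop("weather file is empty: at least one daily record is required",
         call. = FALSE)
  }
  for (col in setdiff(names(raw), "date")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  weather_series(raw, latitude = latitude)
}

#' Write a weather series to CSV
#'
#' Inverse of [read_weather()]: `read_weather(write_weather(ws, f))`
#' reproduces `ws` up to floating-point formatting.
#'
#' @param ws a [weather_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(ws, path) {
  stopifnot(inherits(ws, "weather_series"))
  out <- as.data.frame(ws)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> %d days, %s to %s, latitude %.2f N\n",
              nrow(x), format(x$date[1L]), format(x$date[nrow(x)]),
              attr(x, "latitude")))
  invisible(x)
}

#' Astronomical daylength
#'
#' Daylength in hours from solar declination and sunrise hour angle,
#' using the civil sunrise/sunset convention (sun centre at -0.833
#' degrees altitude, accounting for refraction and the solar disc).
#' Clamped to \[0, 24\] for polar day/night.
#'
#' @param day_of_year integer day of year, 1..366 (vectorised).
#' @param latitude degrees north.
#' @return daylength in hours.
#' @export
photoperiod <- function(day_of_year, latitude) {
  stopifnot(all(day_of_year >= 1 & day_of_year <= 366),
            latitude >= -90, latitude <= 90)
  deg2rad <- pi / 180
  # declination: -23.44 deg at the December solstice (doy ~355)
  decl <- -23.44 * deg2rad * cos(2 * pi * (day_of_year + 10) / 365.25)
  phi <- latitude * deg2rad
  h0 <- -0.833 * deg2rad
  cos_h <- (sin(h0) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cos_h <- pmin(1, pmax(-1, cos_h))
  24 / pi * acos(cos_h)
}

#' Daily thermal time increment
#'
#' Degree-days above a base temperature from the arithmetic mean of the
#' daily temperature extremes: `max(0, (tmin + tmax)/2 - t_base)`.
#'
#' @param tmin,tmax daily minimum and maximum temperature, degrees C.
#' @param t_base base temperature, degrees C.
#' @return degree-days (vectorised).
#' @export
thermal_time_increment <- function(tmin, tmax, t_base = 0) {
  if (any(tmin > tmax)) stop("tmin > tmax", call. = FALSE)
  pmax(0, (tmin + tmax) / 2 - t_base)
}

#' Daily photothermal time increment
#'
#' Thermal time weighted by the fraction of the day with daylight:
#' `dd * daylength / 24`. Photothermal time drives logistic height
#' growth.
#'
#' @param dd degree-days for the day (>= 0).
#' @param daylength hours of daylight, in \[0, 24\].
#' @return photothermal units (vectorised).
#' @export
photothermal_increment <- function(dd, daylength) {
  if (any(dd < 0)) stop("dd must be >= 0", call. = FALSE)
  if (any(daylength < 0 | daylength > 24)) {
    stop("daylength must be in [0, 24]", call. = FALSE)
  }
  dd * daylength / 24
}

#' Daily effective day degrees increment
#'
#' Thermal time down-weighted when incident radiation is scarce:
#' `dd * min(1, radiation / r_ref)`, a saturating linear radiation
#' modifier. Effective day degrees are the biological clock of the
#' sink-limited (early, exponential) green-area phase, capturing that
#' autumn-emerging cohorts expand more slowly under low light at equal
#' temperature.
#'
#' @param dd degree-days for the day (>= 0).
#' @param radiation global radiation, MJ m-2 d-1 (>= 0).
#' @param r_ref reference radiation at which the modifier saturates,
#'   MJ m-2 d-1 (default 10).
#' @return effective degree-days (vectorised).
#' @export
effective_day_degrees_increment <- function(dd, radiation, r_ref = 10) {
  if (any(dd < 0)) stop("dd must be >= 0", call. = FALSE)
  if (any(radiation < 0)) stop("radiation must be >= 0", call. = FALSE)
  if (r_ref <= 0) stop("r_ref must be > 0", call. = FALSE)
  dd * pmin(1, radiation / r_ref)
}
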