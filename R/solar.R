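#' Solar declination (NOAA low-precision approximation)
#'
#' Declination of the sun for a given day of year, from the NOAA
#' fractional-year series expansion. Accuracy is better than 0.2 degrees
#' for years 1900--2100, which is ample for day-length and treatment-time
#' work at temperate latitudes.
#'
#' @param day_of_year Integer day of year (1--366). Vectorized.
#' @param hour Decimal hour used in the fractional-year term; defaults to
#'   solar noon. Sub-day precision is rarely needed.
#' @return Declination in degrees, in approximately \[-23.45, 23.45\].
#' @examples
#' solar_declination(172) # near +23.44 at the June solstice
#' @export
solar_declination <- function(day_of_year, hour = 12) {
  check_day_of_year(day_of_year)
  g <- fractional_year(day_of_year, hour)
  delta <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  delta * 180 / pi
}

#' Equation of time (NOAA low-precision approximation)
#'
#' Signed difference, apparent solar minus mean solar time, driven by the
#' eccentricity of the Earth's orbit and the obliquity of the ecliptic.
#' Ranges roughly from -14 minutes (mid February) to +16 minutes (early
#' November) and integrates to ~0 over a year.
#'
#' @inheritParams solar_declination
#' @return Minutes. Vectorized.
#' @examples
#' equation_of_time(42)  # about -14 minutes
#' equation_of_time(307) # about +16 minutes
#' @export
equation_of_time <- function(day_of_year, hour = 12) {
  check_day_of_year(day_of_year)
  g <- fractional_year(day_of_year, hour)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

fractional_year <- function(day_of_year, hour = 12) {
  2 * pi / 365 * (day_of_year - 1 + (hour - 12) / 24)
}

check_day_of_year <- function(day_of_year) {
  if (any(!is.finite(day_of_year)) ||
      any(day_of_year < 1 | day_of_year > 366)) {
    stop("`day_of_year` must lie in 1..366", call. = FALSE)
  }
  invisible(day_of_year)
}

#' Is EU daylight-saving time active on a date?
#'
#' The EU rule: DST runs from the last Sunday of March to the day before
#' the last Sunday of October. Resolution is one day; fraction times are
#' daytime so the 01:00 UTC transition instant never matters here.
#'
#' @param date A `Date` vector.
#' @return Logical vector.
#' @export
eu_dst_active <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  start <- last_sunday(yr, 3L)
  end <- last_sunday(yr, 10L)
  date >= start & date < end
}

last_sunday <- function(year, month) {
  # last day of the month, stepped back to the preceding Sunday
  first_next <- as.Date(sprintf(
    "%d-%02d-01", ifelse(month == 12L, year + 1L, year),
    ifelse(month == 12L, 1L, month + 1L)
  ))
  last <- first_next - 1L
  last - as.integer(format(last, "%w"))
}

#' Convert local civil time to apparent solar time
#'
#' Apparent solar time = civil clock time minus the zone offset (base UTC
#' offset plus any active daylight-saving offset), plus 4 minutes per
#' degree of east longitude, plus the equation of time; the result is
#' wrapped to \[0, 24). Within one day at one site the conversion is a pure
#' shift, so differences between fraction times are preserved.
#'
#' @param date `Date` vector (or coercible) of the fraction dates.
#' @param clock_time Local civil time of day in decimal hours, in \[0, 24).
#' @param site A single-row site description with fields `longitude`,
#'   `utc_base_offset`, `dst_offset`, `dst_rule` (see [geo_site()]), or a
#'   site table plus `site_name` to select per-row sites.
#' @param utc_offset Optional explicit total UTC offset (hours) per record;
#'   when given it overrides the site's base + DST resolution.
#' @return Apparent solar time in decimal hours from solar midnight.
#' @examples
#' milan <- geo_site("Milan", 45.5, 9.2, utc_base_offset = 1)
#' local_to_solar(as.Date("2015-07-24"), 10, milan) # about 1.5 h behind clock
#' @export
local_to_solar <- function(date, clock_time, site, utc_offset = NULL) {
  date <- as.Date(date)
  if (any(clock_time < 0 | clock_time >= 24)) {
    stop("`clock_time` must lie in [0, 24)", call. = FALSE)
  }
  if (is.null(utc_offset)) {
    rule <- site$dst_rule
    bad <- setdiff(unique(rule), c("EU", "none"))
    if (length(bad)) {
      stop("unknown DST rule '", bad[1],
           "'; supply `utc_offset` explicitly", call. = FALSE)
    }
    dst <- ifelse(rule == "EU" & eu_dst_active(date), site$dst_offset, 0)
    utc_offset <- site$utc_base_offset + dst
  }
  doy <- as.integer(format(date, "%j"))
  solar <- clock_time - utc_offset + site$longitude * 4 / 60 +
    equation_of_time(doy) / 60
  solar %% 24
}

#' Day length from sunrise to sunset
#'
#' Uses the standard sunrise/sunset zenith of 90.833 degrees (atmospheric
#' refraction plus the solar semidiameter). Polar day or night is returned
#' as 24 or 0 hours with a `polar` attribute flagging the affected entries
#' rather than an error.
#'
#' @param date `Date` vector or integer day of year.
#' @param latitude Degrees north.
#' @return Hours of daylight, with attribute `polar` (logical).
#' @examples
#' day_length(as.Date("2015-12-21"), 52.6) # ~7.6 h in Leicester
#' @export
day_length <- function(date, latitude) {
  doy <- to_day_of_year(date)
  delta <- solar_declination(doy) * pi / 180
  phi <- latitude * pi / 180
  x <- (sin(-0.833 * pi / 180) - sin(phi) * sin(delta)) /
    (cos(phi) * cos(delta))
  polar <- x < -1 | x > 1
  x <- pmin(1, pmax(-1, x))
  hours <- 2 * acos(x) * 180 / pi / 15
  attr(hours, "polar") <- polar
  hours
}

#' Maximum solar elevation on a date
#'
#' Elevation of the sun at local solar noon: 90 minus the absolute
#' difference between latitude and declination.
#'
#' @inheritParams day_length
#' @return Degrees above the horizon (negative during polar night).
#' @export
max_solar_elevation <- function(date, latitude) {
  doy <- to_day_of_year(date)
  90 - abs(latitude - solar_declination(doy))
}

to_day_of_year <- function(date) {
  if (inherits(date, "Date") || is.character(date)) {
    as.integer(format(as.Date(date), "%j"))
  } else {
    as.integer(date)
  }
}
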