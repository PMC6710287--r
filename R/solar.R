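# Solar ephemeris (NOAA general solar-position equations) and legal hunting
# hours. Legal hours in the study system run from one hour before sunrise
# until two hours before sunset, in local civil time.

#' Study-area centroid used for solar computations
#'
#' Solar times are computed at a single representative coordinate for the
#' whole study area; at the spatial scale of a telemetry study the
#' within-area difference in sunrise/sunset is under ~2 minutes.
#'
#' @return Named list with `lat`, `lon` (decimal degrees) and `tz`
#'   (Olson timezone name).
#' @export
study_centroid <- function() {
  list(lat = 61, lon = 15, tz = "Europe/Stockholm")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# NOAA solar calculations for a calendar date at longitude `lon`, latitude
# `lat`. Evaluated at 12:00 UTC of the date; the sub-minute drift from not
# iterating on the event time is well inside the tolerance of civil sunrise/
# sunset. Returns sunrise/sunset as minutes past 00:00 UTC.
noaa_sun_events <- function(date, lat, lon) {
  date <- as.Date(date)
  jd <- as.numeric(date) + 2440588      # Julian day at 12:00 UTC
  t <- (jd - 2451545) / 36525           # Julian century

  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m  <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ec <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  ceq <- sin(deg2rad(m)) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(deg2rad(2 * m)) * (0.019993 - 0.000101 * t) +
    sin(deg2rad(3 * m)) * 0.000289
  true_long <- l0 + ceq
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  obliq0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(obliq)) * sin(deg2rad(app_long)))

  y <- tan(deg2rad(obliq / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(l0)) - 2 * ec * sin(deg2rad(m)) +
      4 * ec * y * sin(deg2rad(m)) * cos(2 * deg2rad(l0)) -
      0.5 * y^2 * sin(4 * deg2rad(l0)) - 1.25 * ec^2 * sin(2 * deg2rad(m))
  )

  phi <- deg2rad(lat)
  # zenith 90.833 deg: refraction + solar radius
  cos_ha <- (cos(deg2rad(90.833)) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  if (any(abs(cos_ha) > 1)) {
    stop("polar day or night: sun does not cross the horizon on ", date,
         " at latitude ", lat)
  }
  ha <- rad2deg(acos(cos_ha))
  noon <- 720 - 4 * lon - eqtime
  list(sunrise = noon - 4 * ha, sunset = noon + 4 * ha, noon = noon,
       declination = rad2deg(decl), eqtime = eqtime)
}

#' Sunrise and sunset times
#'
#' Computes civil sunrise and sunset (zenith 90.833 degrees) with the NOAA
#' solar-position equations, returned in the requested local timezone.
#'
#' @param date Date (or coercible) of interest.
#' @param lat,lon Decimal degrees; defaults to the study centroid.
#' @param tz Olson timezone for the returned times.
#' @return List with POSIXct `sunrise` and `sunset`.
#' @export
sun_times <- function(date, lat = study_centroid()$lat,
                      lon = study_centroid()$lon,
                      tz = study_centroid()$tz) {
  date <- as.Date(date)
  ev <- noaa_sun_events(date, lat, lon)
  midnight_utc <- as.POSIXct(format(date), tz = "UTC")
  sr <- midnight_utc + ev$sunrise * 60
  ss <- midnight_utc + ev$sunset * 60
  attr(sr, "tzone") <- tz
  attr(ss, "tzone") <- tz
  list(sunrise = sr, sunset = ss)
}

#' Legal hunting hours for a date
#'
#' Hunting hours last from one hour before sunrise until two hours before
#' sunset (local civil time). Returns the interval together with its
#' duration `D_h` and the complementary nonhunting duration
#' `D_nh = 24 - D_h` hours, the denominators of the daily activity index.
#'
#' @inheritParams sun_times
#' @param sunrise,sunset Optional POSIXct overrides; when supplied the solar
#'   computation is skipped (used in tests and for degenerate inputs).
#' @return List with POSIXct `start`, `end` and numeric `D_h`, `D_nh` (hours).
#' @export
hunting_hours <- function(date, lat = study_centroid()$lat,
                          lon = study_centroid()$lon,
                          tz = study_centroid()$tz,
                          sunrise = NULL, sunset = NULL) {
  if (is.null(sunrise) || is.null(sunset)) {
    st <- sun_times(date, lat, lon, tz)
    sunrise <- st$sunrise
    sunset <- st$sunset
  }
  start <- sunrise - 3600
  end <- sunset - 7200
  d_h <- as.numeric(difftime(end, start, units = "hours"))
  if (d_h <= 0) stop("degenerate hunting interval on ", as.Date(date))
  list(start = start, end = end, D_h = d_h, D_nh = 24 - d_h)
}
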