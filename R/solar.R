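# Day/night classification via standard solar geometry (NOAA-style
# low-precision algorithm, adequate to well under a degree of solar
# elevation). The study site is represented by a single fixed latitude /
# longitude; all timestamps are UTC.

#' Solar elevation angle
#'
#' Computes the elevation of the sun above the horizon for UTC timestamps
#' at a fixed site, using the standard low-precision solar position
#' algorithm (fractional-year Fourier expansions of declination and the
#' equation of time).
#'
#' @param time `POSIXct` timestamps (UTC).
#' @param lat,lon site latitude and longitude in decimal degrees.
#' @return numeric vector of solar elevations in degrees.
#' @export
solar_elevation <- function(time, lat = 55.75, lon = -6.25) {
  stopifnot(inherits(time, "POSIXct"))
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1L
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)   # fractional year, rad
  # equation of time (minutes) and declination (radians)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour * 60 + eqtime + 4 * lon            # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180               # hour angle, rad
  latr <- lat * pi / 180
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

#' Is the sun above the horizon?
#'
#' Day is defined as solar elevation above zero degrees; no twilight band
#' is used.
#'
#' @inheritParams solar_elevation
#' @return logical vector, `TRUE` for daylight.
#' @export
is_daylight <- function(time, lat = 55.75, lon = -6.25) {
  solar_elevation(time, lat, lon) > 0
}

#' Approximate daylight duration for a set of dates
#' @param dates `Date` vector.
#' @inheritParams solar_elevation
#' @return hours of daylight per date (evaluated on a 5-minute grid).
#' @export
daylight_hours <- function(dates, lat = 55.75, lon = -6.25) {
  vapply(dates, function(d) {
    tt <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") +
      seq(0, 86400 - 300, by = 300)
    mean(is_daylight(tt, lat, lon)) * 24
  }, numeric(1))
}
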