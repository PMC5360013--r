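# Solar geometry underlying the threshold method.
#
# Two independent algorithms are provided:
#   * solar_position(): Meeus-series solar coordinates (the algorithm behind
#     the NOAA solar calculator), used throughout the package;
#   * solar_zenith_michalsky(): the Michalsky (1988) almanac, kept as an
#     algorithmically distinct cross-check ephemeris for tests.
# Both are geometric (no atmospheric refraction) which is the convention for
# threshold geolocation: refraction is absorbed by the calibrated zenith.

DEG <- pi / 180

julian_day <- function(time) {
  as.numeric(time) / 86400 + 2440587.5
}

#' Solar ephemeris: declination and equation of time
#'
#' Meeus-series solar coordinates. Accuracy is of order 0.01 degrees over
#' 1950--2050, far below the calibration uncertainty of light-level
#' geolocation.
#'
#' @param time POSIXct (UTC).
#' @return A list with `declination` (degrees), `eqtime` (minutes; apparent
#'   minus mean solar time).
#' @export
solar_ephemeris <- function(time) {
  jc <- (julian_day(time) - 2451545) / 36525

  L0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)

  C <- sin(M * DEG) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * DEG) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * DEG) * 0.000289
  true_long <- L0 + C

  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * DEG)

  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega * DEG)

  decl <- asin(sin(obliq * DEG) * sin(app_long * DEG)) / DEG

  y <- tan(obliq / 2 * DEG)^2
  eqtime <- 4 / DEG * (y * sin(2 * L0 * DEG) - 2 * e * sin(M * DEG) +
    4 * e * y * sin(M * DEG) * cos(2 * L0 * DEG) -
    0.5 * y^2 * sin(4 * L0 * DEG) - 1.25 * e^2 * sin(2 * M * DEG))

  list(declination = decl, eqtime = eqtime)
}

#' Solar zenith angle
#'
#' @param time POSIXct (UTC); recycled against coordinates.
#' @param lat,lon Coordinates in decimal degrees (longitude positive east).
#' @return Zenith angle in degrees (0 = sun overhead, 90 = horizon).
#' @export
solar_zenith <- function(time, lat, lon) {
  eph <- solar_ephemeris(time)
  tst <- (minutes_of_day(time) + eph$eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  cz <- sin(lat * DEG) * sin(eph$declination * DEG) +
    cos(lat * DEG) * cos(eph$declination * DEG) * cos(ha * DEG)
  acos(pmin(1, pmax(-1, cz))) / DEG
}

#' Reference solar zenith (Michalsky almanac)
#'
#' Independent cross-check ephemeris (van Flandern/Pulkkinen style series as
#' given by Michalsky 1988), accurate to about 0.01 degrees over 1950--2050.
#' Used to bound the error of [solar_zenith()]; not used by the pipeline.
#'
#' @inheritParams solar_zenith
#' @return Zenith angle in degrees.
#' @export
solar_zenith_michalsky <- function(time, lat, lon) {
  d <- julian_day(time) - 2451545
  hour_utc <- minutes_of_day(time) / 60

  mnlong <- (280.460 + 0.9856474 * d) %% 360
  mnanom <- ((357.528 + 0.9856003 * d) %% 360) * DEG
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %% 360) * DEG
  oblqec <- (23.439 - 0.0000004 * d) * DEG

  num <- cos(oblqec) * sin(eclong)
  den <- cos(eclong)
  ra <- atan(num / den)
  ra[den < 0] <- ra[den < 0] + pi
  ra[den >= 0 & num < 0] <- ra[den >= 0 & num < 0] + 2 * pi

  dec <- asin(sin(oblqec) * sin(eclong))

  gmst <- (6.697375 + 0.0657098242 * d + hour_utc) %% 24
  lmst <- ((gmst + lon / 15) %% 24) * 15 * DEG
  ha <- lmst - ra
  ha <- ((ha + pi) %% (2 * pi)) - pi

  el <- asin(sin(dec) * sin(lat * DEG) + cos(dec) * cos(lat * DEG) * cos(ha))
  90 - el / DEG
}

#' Analytic twilight time at a fixed zenith angle
#'
#' Solves for the UTC clock time on `date` at which the solar zenith angle
#' equals `zenith` at the given site, on the morning (`rise = TRUE`) or
#' evening side. The hour-angle equation is iterated three times so the
#' ephemeris is evaluated at the event itself.
#'
#' @param date Date (UTC calendar day on which the event's local solar day
#'   is centred).
#' @param lat,lon Site, decimal degrees.
#' @param zenith Zenith angle defining the event, degrees.
#' @param rise Logical; sunrise-side if TRUE.
#' @return POSIXct (UTC), NA when the zenith is never crossed that day
#'   (polar day or night).
#' @export
twilight_time <- function(date, lat, lon, zenith, rise = TRUE) {
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(as.Date(date), n)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  rise <- rep_len(rise, n)

  # initial guess: local solar noon
  t <- utc(paste(format(date), "12:00:00")) - 240 * lon
  for (i in 1:3) {
    eph <- solar_ephemeris(t)
    cH <- (cos(zenith * DEG) - sin(lat * DEG) * sin(eph$declination * DEG)) /
      (cos(lat * DEG) * cos(eph$declination * DEG))
    H <- ifelse(abs(cH) <= 1, acos(pmin(1, pmax(-1, cH))) / DEG, NA_real_)
    minutes <- 720 - 4 * (lon + ifelse(rise, H, -H)) - eph$eqtime
    t <- utc(paste(format(date), "00:00:00")) + 60 * minutes
  }
  t
}

#' Local solar noon
#'
#' @inheritParams twilight_time
#' @return POSIXct (UTC) of solar transit on the site's local solar day.
#' @export
solar_noon <- function(date, lat, lon) {
  n <- max(length(date), length(lon))
  date <- rep_len(as.Date(date), n); lon <- rep_len(lon, n)
  t <- utc(paste(format(date), "12:00:00")) - 240 * lon
  for (i in 1:2) {
    eph <- solar_ephemeris(t)
    t <- utc(paste(format(date), "00:00:00")) + 60 * (720 - 4 * lon - eph$eqtime)
  }
  t
}
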