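# Synthetic world: gridded weather with NCEP-like structure (2.5 degree grid,
# 6-hourly steps) built from deterministic gradients plus AR(1)-in-time,
# spatially smoothed anomalies, and a synthetic land mask. The generator is
# the ground truth for every recovery test downstream.

#' World configuration for the synthetic weather generator
#'
#' @param lat_range,lon_range Grid bounds, degrees (inclusive).
#' @param step Grid step, degrees (default 2.5, reanalysis-like).
#' @param time_step_h Time step in hours (default 6).
#' @param start,end Date span (inclusive).
#' @param seed Integer seed; the same seed yields a bit-identical world.
#' @param temp_gradient Latitudinal temperature gradient, degrees C per
#'   degree latitude (default -0.7).
#' @param temp_ref Temperature at `lat_ref` on the seasonal peak day,
#'   degrees C.
#' @param lat_ref Reference latitude for the gradient, degrees.
#' @param seasonal_amp Seasonal temperature amplitude, degrees C.
#' @param peak_doy Day of year of the seasonal temperature maximum.
#' @param diel_amp Diel temperature amplitude, degrees C (local-hour cycle).
#' @param ar1 AR(1) coefficient of the anomaly fields, in [0, 1).
#' @param noise_sd Named anomaly standard deviations:
#'   `temp` (degC), `sp` (hPa), `wind` (m/s surface), `wind_lev` (m/s aloft).
#' @param sp_ref Mean surface pressure, hPa.
#' @param u_lev_mean Mean zonal wind per pressure level
#'   (1000/925/850/700 mbar), m/s.
#' @param precip_occ Probability a grid cell/time is wet.
#' @param precip_shape,precip_scale Gamma parameters of the wet-cell
#'   precipitation rate (kg/m^2/s).
#' @param land_fraction Approximate fraction of grid cells that are land in
#'   the synthetic mask.
#' @param smooth_passes Smoothing passes applied to anomaly fields (spatial
#'   autocorrelation); 0 disables smoothing.
#' @return A list of class `world_config`.
#' @export
world_config <- function(lat_range = c(-10, 80), lon_range = c(-175, -55),
                         step = 2.5, time_step_h = 6,
                         start = as.Date("2013-08-05"),
                         end = as.Date("2013-11-15"),
                         seed = 1L,
                         temp_gradient = -0.45, temp_ref = 25, lat_ref = 10,
                         seasonal_amp = 12, peak_doy = 190, diel_amp = 2,
                         ar1 = 0.8,
                         noise_sd = c(temp = 4, sp = 6, wind = 3, wind_lev = 5),
                         sp_ref = 1010,
                         u_lev_mean = c(2, 4, 6, 10),
                         precip_occ = 0.25, precip_shape = 0.8,
                         precip_scale = 1e-4,
                         land_fraction = 0.7, smooth_passes = 6) {
  stopifnot_scalar(step, "step", lower = 1e-6)
  stopifnot_scalar(ar1, "ar1", lower = 0, upper = 1 - 1e-12)
  stopifnot(start <= end)
  structure(list(lat_range = lat_range, lon_range = lon_range, step = step,
                 time_step_h = time_step_h, start = as.Date(start),
                 end = as.Date(end), seed = as.integer(seed),
                 temp_gradient = temp_gradient, temp_ref = temp_ref,
                 lat_ref = lat_ref, seasonal_amp = seasonal_amp,
                 peak_doy = peak_doy, diel_amp = diel_amp, ar1 = ar1,
                 noise_sd = noise_sd, sp_ref = sp_ref,
                 u_lev_mean = u_lev_mean, precip_occ = precip_occ,
                 precip_shape = precip_shape, precip_scale = precip_scale,
                 land_fraction = land_fraction,
                 smooth_passes = smooth_passes),
            class = "world_config")
}

# one smoothing pass with a [1 2 1]/4 kernel along both axes (edges clamped)
.smooth_mat <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  up <- m[c(1, seq_len(n1 - 1)), , drop = FALSE]
  dn <- m[c(seq(2, n1), n1), , drop = FALSE]
  m <- 0.5 * m + 0.25 * (up + dn)
  lf <- m[, c(1, seq_len(n2 - 1)), drop = FALSE]
  rt <- m[, c(seq(2, n2), n2), drop = FALSE]
  0.5 * m + 0.25 * (lf + rt)
}

# standardized smooth Gaussian field on the grid
.smooth_noise <- function(nla, nlo, passes) {
  m <- matrix(stats::rnorm(nla * nlo), nla, nlo)
  if (passes > 0) for (i in seq_len(passes)) m <- .smooth_mat(m)
  s <- stats::sd(as.numeric(m))
  if (s > 0) m / s else m
}

#' Generate synthetic gridded weather
#'
#' Deterministic structure (latitudinal temperature gradient, seasonal and
#' diel cycles, level-dependent mean zonal flow) plus AR(1)-in-time,
#' spatially smoothed Gaussian anomalies, and Bernoulli-gamma precipitation.
#' With all noise SDs zero and `precip_occ = 0` the fields reduce to the
#' deterministic terms exactly.
#'
#' @param config A [world_config()].
#' @return An [env_fields()] object with a synthetic land mask attached.
#' @export
make_weather <- function(config) {
  stopifnot(inherits(config, "world_config"))
  lats <- seq(config$lat_range[1], config$lat_range[2], by = config$step)
  lons <- seq(config$lon_range[1], config$lon_range[2], by = config$step)
  if (length(lats) < 2 || length(lons) < 2)
    stop("degenerate grid: a single cell cannot be interpolated")
  # pad one day past the nominal span so sunset-centred windows (+3 h) and
  # overnight flights on the last day stay inside the time hull
  times <- seq(utc(paste(config$start, "00:00:00")),
               utc(paste(config$end + 2, "00:00:00")),
               by = config$time_step_h * 3600)
  nt <- length(times); nla <- length(lats); nlo <- length(lons)

  set.seed(config$seed)
  sds <- config$noise_sd

  ar_field <- function(sd) {
    arr <- array(0, c(nt, nla, nlo))
    if (sd <= 0) return(arr)
    a <- config$ar1
    eps <- .smooth_noise(nla, nlo, config$smooth_passes)   # stationary start
    arr[1, , ] <- sd * eps
    for (t in seq(2, nt)) {
      eps <- a * eps + sqrt(1 - a^2) * .smooth_noise(nla, nlo, config$smooth_passes)
      arr[t, , ] <- sd * eps
    }
    arr
  }

  doy <- as.numeric(strftime(times, "%j", tz = "UTC")) +
    minutes_of_day(times) / 1440
  seasonal <- config$seasonal_amp * cos(2 * pi * (doy - config$peak_doy) / 365.25)
  hour_utc <- minutes_of_day(times) / 60

  temp <- ar_field(sds[["temp"]])
  for (t in seq_len(nt)) {
    local_hour <- outer(rep(1, nla), hour_utc[t] + lons / 15)
    base <- outer(config$temp_ref + config$temp_gradient * (lats - config$lat_ref),
                  rep(1, nlo)) +
      seasonal[t] + config$diel_amp * cos(2 * pi * (local_hour - 14) / 24)
    temp[t, , ] <- temp[t, , ] + base
  }

  sp <- config$sp_ref + ar_field(sds[["sp"]])
  u_sfc <- 2 + ar_field(sds[["wind"]])
  v_sfc <- ar_field(sds[["wind"]])

  nlev <- length(config$u_lev_mean)
  u_lev <- array(0, c(nt, nla, nlo, nlev))
  v_lev <- array(0, c(nt, nla, nlo, nlev))
  for (l in seq_len(nlev)) {
    u_lev[, , , l] <- config$u_lev_mean[l] + ar_field(sds[["wind_lev"]])
    v_lev[, , , l] <- ar_field(sds[["wind_lev"]])
  }

  prate <- array(0, c(nt, nla, nlo))
  if (config$precip_occ > 0) {
    wet <- ar_field(1)
    thresh <- stats::qnorm(1 - config$precip_occ)
    iswet <- wet > thresh
    prate[iswet] <- stats::rgamma(sum(iswet), shape = config$precip_shape,
                                  scale = config$precip_scale)
  }

  # synthetic land mask: smooth blob field thresholded at the requested
  # land fraction
  blob <- .smooth_noise(nla, nlo, max(config$smooth_passes, 4))
  land <- blob > stats::quantile(blob, 1 - config$land_fraction)

  env_fields(times, lats, lons, temp = temp, sp = sp, u_sfc = u_sfc,
             v_sfc = v_sfc, prate = prate, u_lev = u_lev, v_lev = v_lev,
             levels = c(1000, 925, 850, 700), land = land)
}

#' Look up the land mask at a point
#'
#' Nearest-cell lookup; points outside the grid are clamped to the edge.
#'
#' @param fields An [env_fields()] with a land mask.
#' @param lat,lon Coordinates, degrees.
#' @return Logical vector, TRUE over land.
#' @export
is_land <- function(fields, lat, lon) {
  if (is.null(fields$land)) return(rep(TRUE, max(length(lat), length(lon))))
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  ila <- pmin(pmax(round((lat - fields$lats[1]) /
                           (fields$lats[2] - fields$lats[1])) + 1, 1),
              length(fields$lats))
  ilo <- pmin(pmax(round((lon - fields$lons[1]) /
                           (fields$lons[2] - fields$lons[1])) + 1, 1),
              length(fields$lons))
  fields$land[cbind(ila, ilo)]
}
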