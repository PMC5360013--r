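# Environmental annotation: gridded weather fields, space-time interpolation,
# precipitation windows, wind flow assistance, and the bird-day table that
# feeds the reaction-norm models.

#' Construct a gridded weather-field object
#'
#' Container for surface and pressure-level fields on a regular lat/lon grid
#' with a regular UTC time axis. Surface variables are arrays indexed
#' (time, lat, lon); pressure-level winds are indexed
#' (time, lat, lon, level).
#'
#' @param times POSIXct vector (UTC), strictly increasing, regular.
#' @param lats,lons Grid coordinates in decimal degrees, strictly increasing.
#' @param levels Pressure levels in mbar for `u_lev`/`v_lev`
#'   (default 1000, 925, 850, 700).
#' @param temp Surface air temperature, degrees C.
#' @param sp Surface pressure, hPa.
#' @param u_sfc,v_sfc Surface wind components, m/s.
#' @param prate Precipitation rate, kg/m^2/s.
#' @param u_lev,v_lev Wind components at `levels`, m/s.
#' @param land Logical matrix (lat, lon); TRUE over land. Optional.
#' @return An object of class `env_fields`.
#' @export
env_fields <- function(times, lats, lons, temp, sp, u_sfc, v_sfc, prate,
                       u_lev, v_lev, levels = c(1000, 925, 850, 700),
                       land = NULL) {
  nt <- length(times); nla <- length(lats); nlo <- length(lons)
  if (nla < 2 || nlo < 2)
    stop("degenerate grid: need at least 2 latitudes and 2 longitudes")
  if (is.unsorted(times, strictly = TRUE)) stop("'times' must be strictly increasing")
  dim3 <- c(nt, nla, nlo)
  for (nm in c("temp", "sp", "u_sfc", "v_sfc", "prate")) {
    x <- get(nm)
    if (!identical(dim(x), as.integer(dim3)))
      stop(sprintf("field '%s' must have dim (time, lat, lon) = (%d, %d, %d)",
                   nm, nt, nla, nlo))
  }
  dim4 <- as.integer(c(dim3, length(levels)))
  if (!identical(dim(u_lev), dim4) || !identical(dim(v_lev), dim4))
    stop("level winds must have dim (time, lat, lon, level)")
  structure(list(temp = temp, sp = sp, u_sfc = u_sfc, v_sfc = v_sfc,
                 prate = prate, u_lev = u_lev, v_lev = v_lev,
                 times = times, lats = lats, lons = lons, levels = levels,
                 land = land),
            class = "env_fields")
}

#' @export
print.env_fields <- function(x, ...) {
  cat(sprintf(
    "<env_fields> %d times (%s .. %s), %d x %d grid (lat %.1f..%.1f, lon %.1f..%.1f), levels: %s\n",
    length(x$times), format(min(x$times), tz = "UTC"),
    format(max(x$times), tz = "UTC"),
    length(x$lats), length(x$lons), min(x$lats), max(x$lats),
    min(x$lons), max(x$lons), paste(x$levels, collapse = "/")))
  invisible(x)
}

# index and weight along one regular axis; errors when outside the hull
.axis_locate <- function(q, axis, name) {
  if (any(!is.finite(q))) stop(sprintf("non-finite query on axis '%s'", name))
  if (any(q < axis[1] | q > axis[length(axis)]))
    stop(sprintf("query outside grid hull on axis '%s'", name))
  i <- findInterval(q, axis, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(axis) - 1L)
  w <- (q - axis[i]) / (axis[i + 1L] - axis[i])
  list(i = i, w = w)
}

#' Interpolate a gridded field in space and time
#'
#' Bilinear in latitude/longitude, linear in time; pressure levels are
#' matched exactly (the four discrete levels are not interpolated across).
#' Queries outside the grid hull are an error naming the offending axis
#' (time extrapolation is forbidden).
#'
#' @param fields An [env_fields()] object.
#' @param var One of `"temp"`, `"sp"`, `"u_sfc"`, `"v_sfc"`, `"prate"`,
#'   `"u_lev"`, `"v_lev"`.
#' @param time POSIXct query times (UTC).
#' @param lat,lon Query coordinates, degrees.
#' @param level Pressure level in mbar, required for level variables.
#' @return Interpolated values (vector).
#' @export
interp_field <- function(fields, var, time, lat, lon, level = NULL) {
  stopifnot(inherits(fields, "env_fields"))
  arr <- fields[[var]]
  if (is.null(arr)) stop(sprintf("unknown field '%s'", var))
  n <- max(length(time), length(lat), length(lon))
  tq <- rep_len(as.numeric(time), n)
  laq <- rep_len(lat, n); loq <- rep_len(lon, n)

  at <- .axis_locate(tq, as.numeric(fields$times), "time")
  ala <- .axis_locate(laq, fields$lats, "lat")
  alo <- .axis_locate(loq, fields$lons, "lon")

  if (length(dim(arr)) == 4L) {
    if (is.null(level)) stop(sprintf("field '%s' needs a 'level'", var))
    il <- match(level, fields$levels)
    if (is.na(il)) stop(sprintf("level %s not in grid levels (%s)", level,
                                paste(fields$levels, collapse = ", ")))
    nt <- dim(arr)[1]; nla <- dim(arr)[2]; nlo <- dim(arr)[3]
    off <- (il - 1L) * nt * nla * nlo
    lin <- function(it, ila, ilo) arr[off + it + (ila - 1L) * nt + (ilo - 1L) * nt * nla]
  } else {
    nt <- dim(arr)[1]; nla <- dim(arr)[2]
    lin <- function(it, ila, ilo) arr[it + (ila - 1L) * nt + (ilo - 1L) * nt * nla]
  }

  bil <- function(it) {
    v00 <- lin(it, ala$i, alo$i);         v10 <- lin(it, ala$i + 1L, alo$i)
    v01 <- lin(it, ala$i, alo$i + 1L);    v11 <- lin(it, ala$i + 1L, alo$i + 1L)
    (1 - ala$w) * ((1 - alo$w) * v00 + alo$w * v01) +
      ala$w * ((1 - alo$w) * v10 + alo$w * v11)
  }
  (1 - at$w) * bil(at$i) + at$w * bil(at$i + 1L)
}

#' Precipitation summed around local sunset
#'
#' Sum of the interpolated precipitation rate at the 7 hourly steps spanning
#' sunset - 3 h to sunset + 3 h.
#'
#' @param fields An [env_fields()] object.
#' @param sunset POSIXct (UTC) local sunset time.
#' @param lat,lon Location, degrees.
#' @return Precipitation sum (kg/m^2/s summed over the 7 samples).
#' @export
precip_window <- function(fields, sunset, lat, lon) {
  n <- max(length(sunset), length(lat), length(lon))
  sunset <- rep_len(sunset, n); lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  vapply(seq_len(n), function(k) {
    tt <- sunset[k] + 3600 * (-3:3)
    sum(interp_field(fields, "prate", tt, lat[k], lon[k]))
  }, numeric(1))
}

#' Wind flow assistance toward a preferred direction
#'
#' The airspeed-based flow-assistance measure
#' \deqn{fa = y\cos\theta + \sqrt{z^2 - (y\sin\theta)^2} - z}
#' where `y` is wind speed, `z` the bird's airspeed and \eqn{\theta} the
#' angle between the direction the wind blows toward and the preferred track
#' direction. When the crosswind component exceeds the airspeed
#' (\eqn{(y\sin\theta)^2 > z^2}) the bird cannot compensate and the value is
#' missing (`NA`), not an error.
#'
#' @param u,v Wind components, m/s (u eastward, v northward).
#' @param pref_dir Preferred direction of movement, degrees clockwise from
#'   north.
#' @param z Airspeed, m/s (default 13).
#' @return Flow assistance in m/s, `NA` where undefined.
#' @export
flow_assistance <- function(u, v, pref_dir, z = 13) {
  if (any(z <= 0)) stop("airspeed 'z' must be positive")
  y <- sqrt(u^2 + v^2)
  wind_to <- atan2(u, v) / DEG          # direction wind blows toward, deg from N
  theta <- (wind_to - pref_dir) * DEG
  cross2 <- (y * sin(theta))^2
  out <- y * cos(theta) + sqrt(pmax(z^2 - cross2, 0)) - z
  out[cross2 > z^2] <- NA_real_
  out
}

#' Best flow assistance across pressure levels
#'
#' Flow assistance toward a goal evaluated at each pressure level of the
#' field, returning the maximum; missing levels are ignored and the result
#' is missing only if every level is missing.
#'
#' @param fields An [env_fields()] object.
#' @param time POSIXct (UTC).
#' @param lat,lon Current location, degrees.
#' @param goal_lat,goal_lon Next migratory goal, degrees.
#' @param z Airspeed, m/s.
#' @return Best flow assistance (m/s) or `NA`.
#' @export
best_flow <- function(fields, time, lat, lon, goal_lat, goal_lon, z = 13) {
  brg <- gc_bearing(lat, lon, goal_lat, goal_lon)
  fa <- vapply(fields$levels, function(lv) {
    u <- interp_field(fields, "u_lev", time, lat, lon, level = lv)
    v <- interp_field(fields, "v_lev", time, lat, lon, level = lv)
    flow_assistance(u, v, brg, z)
  }, numeric(1))
  if (all(is.na(fa))) NA_real_ else max(fa, na.rm = TRUE)
}

#' Mean hourly flow assistance along a night's flight path
#'
#' Places the bird at hourly steps along the great circle from `from` to
#' `to` between `t_start` and `t_end`, evaluates [best_flow()] toward the
#' endpoint at each hour with winds interpolated in space and time, and
#' returns the mean. Missing hours are ignored; the result is missing only
#' if every hour is missing.
#'
#' @param fields An [env_fields()] object.
#' @param from_lat,from_lon,to_lat,to_lon Endpoints of the flight, degrees.
#' @param t_start,t_end POSIXct (UTC) start and end of the night.
#' @param z Airspeed, m/s.
#' @return Mean flow assistance, m/s, or `NA`.
#' @export
hourly_mean_flow <- function(fields, from_lat, from_lon, to_lat, to_lon,
                             t_start, t_end, z = 13) {
  hrs <- as.numeric(difftime(t_end, t_start, units = "hours"))
  if (!is.finite(hrs) || hrs <= 0) stop("zero-length night")
  tt <- seq(t_start, t_end, by = "1 hour")
  frac <- as.numeric(difftime(tt, t_start, units = "hours")) / hrs
  total <- gc_distance_km(from_lat, from_lon, to_lat, to_lon)
  brg0 <- gc_bearing(from_lat, from_lon, to_lat, to_lon)
  pos <- gc_destination(from_lat, from_lon, brg0, frac * total)
  fa <- vapply(seq_along(tt), function(k) {
    if (total * (1 - frac[k]) < 1e-6) return(NA_real_)  # at the goal: bearing undefined
    best_flow(fields, tt[k], pos$lat[k], pos$lon[k], to_lat, to_lon, z)
  }, numeric(1))
  if (all(is.na(fa))) NA_real_ else mean(fa, na.rm = TRUE)
}

#' Build the model-ready bird-day table
#'
#' One row per day of the migration window: stopover days carry the binary
#' departure response (1 on the last evening of a stopover), travel days
#' carry the realized travel speed (km/day, the overnight displacement into
#' that day). Each row is annotated with sunset-time weather, the
#' precipitation window sum, best flow assistance across pressure levels
#' toward the seasonal destination (stopover rows) or the mean hourly flow
#' along the night's path (travel rows), and the remaining migration
#' distance.
#'
#' @param schedule A `migration_schedule` from [build_schedule()].
#' @param track A track data frame (columns `date`, `lat`, `lon`, `lat_sd`,
#'   `sunrise`, `sunset`), typically from [refine_track()].
#' @param fields An [env_fields()] object covering the window.
#' @param destination `c(lat, lon)` of the seasonal destination used for
#'   remaining distance and stopover-row bearings.
#' @param bird_id Identifier copied into the table.
#' @param year Deployment year (random-effect factor level).
#' @param airspeed Airspeed for flow assistance, m/s.
#' @return A data.frame of class `bird_day_table`; rows with missing flow
#'   assistance are flagged, not dropped (model fits drop them listwise and
#'   report the count).
#' @export
build_bird_day_table <- function(schedule, track, fields, destination,
                                 bird_id = "bird1", year = 1L, airspeed = 13) {
  days <- schedule$days
  if (!all(days$date %in% track$date))
    stop("schedule/track date mismatch: schedule days missing from track")
  tr <- track[match(days$date, track$date), ]

  n <- nrow(days)
  out <- data.frame(
    bird = bird_id, year = year, date = days$date, day_type = days$state,
    lat = NA_real_, lon = NA_real_, stringsAsFactors = FALSE)
  out$sunset <- tr$sunset

  # stopover rows sit at their period's mean location; travel rows at the
  # day's own estimate
  out$lat <- tr$lat; out$lon <- tr$lon
  periods <- schedule$periods
  if (nrow(periods) > 0) {
    for (p in seq_len(nrow(periods))) {
      sel <- days$date >= periods$start[p] & days$date <= periods$end[p] &
        days$state == "stopover"
      out$lat[sel] <- periods$lat[p]
      out$lon[sel] <- periods$lon[p]
    }
  }

  out$temperature <- interp_field(fields, "temp", out$sunset, out$lat, out$lon)
  out$pressure <- interp_field(fields, "sp", out$sunset, out$lat, out$lon)
  u <- interp_field(fields, "u_sfc", out$sunset, out$lat, out$lon)
  v <- interp_field(fields, "v_sfc", out$sunset, out$lat, out$lon)
  out$wind_speed <- sqrt(u^2 + v^2)
  out$precipitation <- precip_window(fields, out$sunset, out$lat, out$lon)
  out$remaining_distance <- gc_distance_km(out$lat, out$lon,
                                           destination[1], destination[2])

  idx <- match(days$date, track$date)
  out$flow_assistance <- NA_real_
  for (k in seq_len(n)) {
    if (days$state[k] == "travel" && k > 1) {
      prev <- idx[k] - 1L
      if (prev >= 1 && gc_distance_km(track$lat[prev], track$lon[prev],
                                      tr$lat[k], tr$lon[k]) > 1) {
        out$flow_assistance[k] <- hourly_mean_flow(
          fields, track$lat[prev], track$lon[prev], tr$lat[k], tr$lon[k],
          track$sunset[prev], tr$sunrise[k], z = airspeed)
        next
      }
    }
    if (out$remaining_distance[k] > 1e-6)
      out$flow_assistance[k] <- best_flow(fields, out$sunset[k], out$lat[k],
                                          out$lon[k], destination[1],
                                          destination[2], z = airspeed)
  }

  # responses
  out$departure <- NA_integer_
  st <- which(days$state == "stopover")
  nxt <- match(days$date + 1, days$date)
  out$departure[st] <- as.integer(!is.na(nxt[st]) & days$state[nxt[st]] == "travel")
  out$travel_speed <- NA_real_
  twl <- which(days$state == "travel")
  for (k in twl) {
    prev <- idx[k] - 1L
    if (prev >= 1)
      out$travel_speed[k] <- gc_distance_km(track$lat[prev], track$lon[prev],
                                            tr$lat[k], tr$lon[k])
  }
  out$lat_sd <- tr$lat_sd
  out$flow_missing <- is.na(out$flow_assistance)
  class(out) <- c("bird_day_table", "data.frame")
  out
}
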