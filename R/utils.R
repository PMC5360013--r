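# Shared small helpers: great-circle geometry, angle wrapping, time handling.

EARTH_RADIUS_KM <- 6371

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are recycled.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @export
gc_distance_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial great-circle bearing
#'
#' @inheritParams gc_distance_km
#' @return Bearing in degrees clockwise from geographic north, in
#'   (-180, 180].
#' @export
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  b <- geosphere::bearing(cbind(rep_len(lon1, n), rep_len(lat1, n)),
                          cbind(rep_len(lon2, n), rep_len(lat2, n)))
  wrap_lon(b)
}

#' Destination point along a great circle
#'
#' @inheritParams gc_distance_km
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param dist_km Distance to travel, km.
#' @return A list with elements `lat` and `lon` (degrees).
#' @export
gc_destination <- function(lat1, lon1, bearing, dist_km) {
  n <- max(length(lat1), length(lon1), length(bearing), length(dist_km))
  p <- geosphere::destPoint(cbind(rep_len(lon1, n), rep_len(lat1, n)),
                            rep_len(bearing, n),
                            rep_len(dist_km, n) * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  list(lat = p[, 2], lon = wrap_lon(p[, 1]))
}

#' Wrap longitudes into (-180, 180]
#'
#' @param lon Longitudes or angular differences in degrees.
#' @return Wrapped values.
#' @export
wrap_lon <- function(lon) {
  out <- (lon + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

# POSIXct constructor pinned to UTC; all internal times are UTC.
utc <- function(x, format = "%Y-%m-%d %H:%M:%S") {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC", format = format)
}

utc_date <- function(t) as.Date(t, tz = "UTC")

# Minutes past UTC midnight of the event's own UTC day.
minutes_of_day <- function(t) {
  as.numeric(difftime(t, trunc(t, "days"), units = "mins"))
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
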