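# Shared fixture builders: every fixture is generated in code.

# twilight set at a fixed site (optionally log-normal shaded), or straight
# from a truth record's shaded twilight columns
make_site_twilights <- function(ndays, site, zenith = 96.8,
                                meanlog = 2.2, sdlog = 1.0, shading = TRUE,
                                start = as.Date("2013-09-01")) {
  dates <- seq(start, by = "1 day", length.out = ndays)
  rs <- twilight_time(dates, site[1], site[2], zenith, rise = TRUE)
  ss <- twilight_time(dates, site[1], site[2], zenith, rise = FALSE)
  d1 <- if (shading) stats::rlnorm(ndays, meanlog, sdlog) else rep(0, ndays)
  d2 <- if (shading) stats::rlnorm(ndays, meanlog, sdlog) else rep(0, ndays)
  tw <- data.frame(date = rep(dates, 2),
                   type = rep(c("sunrise", "sunset"), each = ndays),
                   time = c(rs + 60 * d1, ss - 60 * d2), flag = "kept",
                   original_time = as.POSIXct(NA, tz = "UTC"))
  tw <- tw[order(tw$time), ]
  rownames(tw) <- NULL
  class(tw) <- c("twilight_set", "data.frame")
  tw
}

truth_twilights <- function(truth) {
  ok <- !truth$polar
  tw <- data.frame(date = rep(truth$date[ok], 2),
                   type = rep(c("sunrise", "sunset"), each = sum(ok)),
                   time = c(truth$rise_shaded[ok], truth$set_shaded[ok]),
                   flag = "kept",
                   original_time = as.POSIXct(NA, tz = "UTC"))
  tw <- tw[order(tw$time), ]
  rownames(tw) <- NULL
  class(tw) <- c("twilight_set", "data.frame")
  tw
}

# small analytic weather object: linear-in-space fields, constant winds
make_constant_fields <- function(start = utc("2013-08-01 00:00:00"),
                                 hours = 72, step_h = 6,
                                 lats = seq(0, 70, 2.5),
                                 lons = seq(-170, -60, 2.5),
                                 temp_fun = function(t, la, lo) 25 - 0.5 * la,
                                 u = 5, v = 0, prate = 0,
                                 u_levels = NULL) {
  times <- seq(start, by = step_h * 3600, length.out = hours / step_h + 1)
  nt <- length(times); nla <- length(lats); nlo <- length(lons)
  temp <- array(0, c(nt, nla, nlo))
  for (it in seq_len(nt))
    temp[it, , ] <- outer(lats, lons, function(la, lo)
      temp_fun(times[it], la, lo))
  cst <- function(val) array(val, c(nt, nla, nlo))
  u_lev <- array(NA_real_, c(nt, nla, nlo, 4))
  v_lev <- array(0, c(nt, nla, nlo, 4))
  if (is.null(u_levels)) u_levels <- rep(u, 4)
  for (l in 1:4) u_lev[, , , l] <- u_levels[l]
  env_fields(times, lats, lons, temp = temp, sp = cst(1010),
             u_sfc = cst(u), v_sfc = cst(v), prate = cst(prate),
             u_lev = u_lev, v_lev = v_lev)
}

# default small world + agent for end-to-end style tests
small_world <- function(seed = 11, end = as.Date("2013-09-20"), ...) {
  wc <- world_config(seed = seed, end = end, ...)
  list(config = wc, fields = make_weather(wc))
}

fixed_calibration <- function(zenith = 96.8, meanlog = 2.2, sdlog = 1.0) {
  structure(list(zenith = zenith, meanlog = meanlog, sdlog = sdlog,
                 n = NA, degenerate = FALSE),
            class = "calibration")
}
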