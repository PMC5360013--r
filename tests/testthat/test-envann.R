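# Interpolation, precipitation windows, flow assistance and the bird-day table.

test_that("interpolation reproduces grid nodes and linear fields exactly", {
  f <- make_constant_fields(temp_fun = function(t, la, lo) 2 * lo + 30)
  expect_equal(interp_field(f, "temp", f$times[2], f$lats[4], f$lons[6]),
               2 * f$lons[6] + 30)
  # mid-cell query on a field linear in lon is exact
  lon_mid <- (f$lons[6] + f$lons[7]) / 2 + 0.3
  expect_equal(interp_field(f, "temp", f$times[2], 30, lon_mid),
               2 * lon_mid + 30, tolerance = 1e-12)
})

test_that("interpolation error shrinks quadratically with grid refinement", {
  g <- function(la, lo) sin(la / 10) * cos(lo / 15)
  errs <- sapply(c(5, 2.5, 1.25), function(st) {
    lats <- seq(20, 60, st); lons <- seq(-140, -80, st)
    f <- make_constant_fields(lats = lats, lons = lons,
                              temp_fun = function(t, la, lo) g(la, lo))
    set.seed(1)
    qla <- runif(200, 25, 55); qlo <- runif(200, -135, -85)
    max(abs(interp_field(f, "temp", f$times[1], qla, qlo) - g(qla, qlo)))
  })
  # halving the step should cut the error by ~4; allow 3 for safety
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("out-of-hull queries error naming the axis", {
  f <- make_constant_fields()
  expect_error(interp_field(f, "temp", f$times[1] - 3600, 30, -100), "time")
  expect_error(interp_field(f, "temp", f$times[2], 89, -100), "lat")
  expect_error(interp_field(f, "temp", f$times[2], 30, 10), "lon")
})

test_that("precipitation window sums 7 hourly samples", {
  f <- make_constant_fields(prate = 3e-4, hours = 96)
  sunset <- f$times[1] + 12 * 3600
  expect_equal(precip_window(f, sunset, 30, -100), 7 * 3e-4, tolerance = 1e-12)
  f0 <- make_constant_fields(prate = 0, hours = 96)
  expect_equal(precip_window(f0, sunset, 30, -100), 0)
  # triangular pulse in time, centred on sunset: hand-computed 7-point sum
  fp <- make_constant_fields(hours = 96)
  peak_i <- which.min(abs(as.numeric(fp$times) - as.numeric(sunset)))
  rate <- pmax(0, 1 - abs(as.numeric(fp$times) - as.numeric(fp$times[peak_i])) / (3 * 3600))
  for (it in seq_along(fp$times)) fp$prate[it, , ] <- rate[it]
  hrs <- sunset + 3600 * (-3:3)
  expected <- sum(approx(as.numeric(fp$times), rate, as.numeric(hrs))$y)
  expect_equal(precip_window(fp, sunset, 30, -100), expected, tolerance = 1e-10)
})

test_that("flow assistance obeys its closed-form identities", {
  # theta = 0: pure tailwind adds fully, for any wind below the airspeed
  for (y in c(0.5, 5, 12.9))
    expect_equal(flow_assistance(u = 0, v = y, pref_dir = 0, z = 13), y,
                 tolerance = 1e-9)
  expect_equal(flow_assistance(0, -5, 0, 13), -5)                # head wind
  expect_equal(flow_assistance(5, 0, 0, 13), sqrt(169 - 25) - 13) # crosswind: -1
  expect_true(is.na(flow_assistance(14, 0, 0, 13)))              # uncompensable
  expect_error(flow_assistance(1, 1, 0, z = 0), "positive")
})

test_that("best flow equals the max over levels and dominates each one", {
  f <- make_constant_fields(u_levels = c(-8, -2, 3, 10))
  t0 <- f$times[2]
  # eastward goal: bearing 90, tailwind level u=10 wins
  bf <- best_flow(f, t0, 30, -120, 30, -100, z = 13)
  singles <- sapply(f$levels, function(lv)
    flow_assistance(interp_field(f, "u_lev", t0, 30, -120, level = lv),
                    interp_field(f, "v_lev", t0, 30, -120, level = lv),
                    gc_bearing(30, -120, 30, -100), 13))
  expect_equal(bf, max(singles, na.rm = TRUE))
  expect_true(all(bf >= singles | is.na(singles)))
})

test_that("hourly mean flow matches a brute-force per-hour loop", {
  f <- make_constant_fields(u_levels = c(2, 4, 6, 8), hours = 96)
  from <- c(40, -130); to <- c(38, -110)
  t0 <- f$times[3]; t1 <- t0 + 8 * 3600
  got <- hourly_mean_flow(f, from[1], from[2], to[1], to[2], t0, t1, z = 13)
  tt <- seq(t0, t1, by = "1 hour")
  total <- gc_distance_km(from[1], from[2], to[1], to[2])
  brg <- gc_bearing(from[1], from[2], to[1], to[2])
  fa <- numeric(0)
  for (k in seq_along(tt)) {
    fr <- as.numeric(difftime(tt[k], t0, units = "hours")) /
      as.numeric(difftime(t1, t0, units = "hours"))
    pos <- gc_destination(from[1], from[2], brg, fr * total)
    if (total * (1 - fr) < 1e-6) next
    fa <- c(fa, best_flow(f, tt[k], pos$lat, pos$lon, to[1], to[2], 13))
  }
  expect_equal(got, mean(fa), tolerance = 1e-12)
  # uniform wind along a meridian (constant bearing): equals the point value
  fu <- make_constant_fields(u_levels = rep(5, 4), hours = 96)
  got_u <- hourly_mean_flow(fu, 45, -120, 35, -120, t0, t1, z = 13)
  expect_equal(got_u, best_flow(fu, t0, 45, -120, 35, -120, 13),
               tolerance = 1e-9)
  expect_error(hourly_mean_flow(f, 40, -130, 38, -110, t0, t0), "zero-length")
})

test_that("the bird-day table matches the simulator's bookkeeping", {
  sw <- small_world(seed = 8)
  ag <- agent_config()
  tr <- suppressWarnings(simulate_track(ag, sw$fields, sw$config, seed = 2))
  # perfect-knowledge schedule/track built from truth
  track <- data.frame(date = tr$date, lat = tr$lat, lon = tr$lon,
                      lat_sd = 0.5, sunrise = tr$rise_true, sunset = tr$set_true)
  r <- rle(tr$state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values == "stopover")
  periods <- do.call(rbind, lapply(seq_along(keep), function(j) {
    k <- keep[j]
    data.frame(id = j, start = tr$date[starts[k]], end = tr$date[ends[k]],
               lat = mean(tr$lat[starts[k]:ends[k]]),
               lon = mean(tr$lon[starts[k]:ends[k]]),
               duration = r$lengths[k], merged_from = as.character(j))
  }))
  days <- data.frame(date = tr$date, state = tr$state, lat = tr$lat,
                     lon = tr$lon, displacement_km = tr$displacement_km)
  sched <- structure(list(periods = periods, days = days,
                          onset = tr$date[1], termination = max(tr$date),
                          truncated = FALSE),
                     class = "migration_schedule")
  bd <- build_bird_day_table(sched, track, sw$fields, ag$wintering)
  expect_equal(nrow(bd), nrow(tr))
  expect_equal(sum(bd$day_type == "stopover"), sum(tr$state == "stopover"))
  # departure = 1 exactly on the last evening of each stopover
  expect_equal(sum(bd$departure == 1, na.rm = TRUE),
               sum(tr$state == "stopover" &
                     c(tr$state[-1], "stopover") == "travel"))
  # remaining distance 0 at the destination
  at_dest <- which(gc_distance_km(tr$lat, tr$lon, ag$wintering[1],
                                  ag$wintering[2]) < 1)
  if (length(at_dest))
    expect_lt(max(bd$remaining_distance[at_dest]), 1)
  # remaining distance non-increasing within positional error
  expect_true(all(diff(bd$remaining_distance) < 50))
  # deterministic rebuild
  bd2 <- build_bird_day_table(sched, track, sw$fields, ag$wintering)
  expect_identical(bd$flow_assistance, bd2$flow_assistance)
})
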