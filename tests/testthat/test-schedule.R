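# Changepoint probabilities, segmentation, merging, season rules, metrics.

# true stationary periods under the study's own operational definition:
# sites within the merge radius are one site
truth_periods <- function(tr, radius = 200) {
  r <- rle(tr$state); e2 <- cumsum(r$lengths); s2 <- e2 - r$lengths + 1
  ks <- which(r$values == "stopover")
  p <- do.call(rbind, lapply(seq_along(ks), function(j) {
    k <- ks[j]
    data.frame(id = j, start = tr$date[s2[k]], end = tr$date[e2[k]],
               lat = mean(tr$lat[s2[k]:e2[k]]), lon = mean(tr$lon[s2[k]:e2[k]]),
               duration = r$lengths[k], merged_from = as.character(j))
  }))
  p <- merge_neighbours(p, radius)
  p[as.numeric(p$end - p$start) >= 1, ]
}

recovered_periods <- function(tr, q = 0.75) {
  twt <- truth_twilights(tr)
  track <- data.frame(date = tr$date, lat = tr$lat, lon = tr$lon)
  per <- segment_track(twt, track, q = q, min_days = 1)
  per <- merge_neighbours(per, 200)
  per[as.numeric(per$end - per$start) >= 1, ]
}

test_that("constant twilight series has uniformly low changepoint probability", {
  # an artificial strictly constant series (same clock times every day) plus
  # tiny jitter: nothing should look like movement
  set.seed(3)
  dates <- seq(as.Date("2013-09-01"), by = 1, length.out = 25)
  tw <- data.frame(date = rep(dates, 2),
                   type = rep(c("sunrise", "sunset"), each = 25),
                   time = c(utc(paste(dates, "06:30:00")),
                            utc(paste(dates, "18:15:00"))) + rnorm(50, 0, 30),
                   flag = "kept", original_time = as.POSIXct(NA, tz = "UTC"))
  class(tw) <- c("twilight_set", "data.frame")
  cp <- changepoint_probabilities(tw, window = 6)
  expect_lt(quantile(cp$prob, 0.9), 0.99)
  expect_lt(max(cp$score), 12)   # no event stands out as a level shift
})

test_that("a single step is assigned maximum probability at the step event", {
  set.seed(4)
  dates <- seq(as.Date("2013-09-01"), by = 1, length.out = 20)
  mk <- function(hms) utc(paste(dates, hms)) + rnorm(20, 0, 60)
  tw <- data.frame(date = rep(dates, 2),
                   type = rep(c("sunrise", "sunset"), each = 20),
                   time = c(mk("06:30:00"), mk("18:15:00")),
                   flag = "kept", original_time = as.POSIXct(NA, tz = "UTC"))
  class(tw) <- c("twilight_set", "data.frame")
  ss <- which(tw$type == "sunset")
  tw$time[ss[11:20]] <- tw$time[ss[11:20]] + 20 * 60   # 20-min step at event 11
  cp <- changepoint_probabilities(tw, window = 6)
  cps <- cp[cp$type == "sunset", ]
  expect_equal(which.max(cps$score), 11)
  expect_error(changepoint_probabilities(tw, window = 50), "need at least")
})

test_that("quantile saturation collapses everything into one stationary period", {
  sw <- small_world(seed = 9)
  ag <- agent_config()
  tr <- suppressWarnings(simulate_track(ag, sw$fields, sw$config, seed = 4))
  tw <- truth_twilights(tr)
  track <- data.frame(date = tr$date, lat = tr$lat, lon = tr$lon)
  hi <- segment_track(tw, track, q = 1)
  expect_equal(nrow(hi), 1)
  expect_equal(as.numeric(hi$end - hi$start) + 1, nrow(track))
})

test_that("merging respects the radius and iterates to a fixed point", {
  mk <- function(lat, lon, start, dur)
    data.frame(id = 1, start = as.Date(start),
               end = as.Date(start) + dur - 1, lat = lat, lon = lon,
               duration = dur, merged_from = "x")
  # 150 km apart: merge; 500 km apart: keep
  p <- rbind(mk(50, -100, "2013-09-01", 3), mk(50 + 150 / 111.2, -100, "2013-09-06", 3),
             mk(50 + 650 / 111.2, -100, "2013-09-12", 4))
  m <- merge_neighbours(p, 200)
  expect_equal(nrow(m), 2)
  expect_equal(m$duration[1], 6)
  expect_equal(m$start[1], as.Date("2013-09-01"))
  expect_equal(m$end[1], as.Date("2013-09-08"))
  # three collinear at 0 / 150 / 300 km: first two merge, the merged mean
  # (duration-weighted) is re-tested against the third
  p3 <- rbind(mk(50, -100, "2013-09-01", 3),
              mk(50 + 150 / 111.2, -100, "2013-09-06", 3),
              mk(50 + 300 / 111.2, -100, "2013-09-12", 3))
  m3 <- merge_neighbours(p3, 200)
  # merged mean sits at 75 km; 300 km site is 225 km away: stays separate
  expect_equal(nrow(m3), 2)
  # idempotence at the fixed point
  expect_equal(nrow(merge_neighbours(m3, 200)), nrow(m3))
  m500 <- merge_neighbours(rbind(mk(50, -100, "2013-09-01", 3),
                                 mk(50 + 500 / 111.2, -100, "2013-09-06", 3)), 200)
  expect_equal(nrow(m500), 2)
})

test_that("autumn onset follows the 2-degree longitude rule", {
  mk <- function(lat, lon, start, dur)
    data.frame(id = 1, start = as.Date(start), end = as.Date(start) + dur - 1,
               lat = lat, lon = lon, duration = dur, merged_from = "x")
  breeding <- c(65, -145)
  track <- data.frame(date = seq(as.Date("2013-08-01"), as.Date("2013-10-01"), 1),
                      lat = 60, lon = -120)
  # direction of travel is eastward: sites at 1 deg then 5 deg east
  p <- rbind(mk(65, -145, "2013-08-01", 5),
             mk(64, -144, "2013-08-08", 3),
             mk(60, -140, "2013-08-15", 4),
             mk(30, -100, "2013-09-10", 20))
  ssn <- define_season(p, track, breeding, wintering = c(30, -100), "autumn")
  # onset = start of the flight run preceding the 5-degree site: day after
  # the 1-degree stopover ends
  expect_equal(ssn$onset, as.Date("2013-08-11"))
  expect_equal(ssn$termination, as.Date("2013-09-10"))
  # all stopovers within 2 degrees: last day of the subsequent flight run
  p2 <- rbind(mk(65, -145, "2013-08-01", 5), mk(64.5, -144.5, "2013-08-08", 3))
  ssn2 <- define_season(p2, track, breeding, wintering = c(64, -144.9), "autumn")
  expect_equal(ssn2$onset, max(track$date))
})

test_that("spring truncation is flagged when breeding is never reached", {
  mk <- function(lat, lon, start, dur)
    data.frame(id = 1, start = as.Date(start), end = as.Date(start) + dur - 1,
               lat = lat, lon = lon, duration = dur, merged_from = "x")
  breeding <- c(65, -145); wintering <- c(12, -95)
  track <- data.frame(date = seq(as.Date("2014-03-20"), as.Date("2014-05-10"), 1),
                      lat = seq(12, 50, length.out = 52),
                      lon = seq(-95, -130, length.out = 52))
  p <- rbind(mk(12, -95, "2014-03-20", 10), mk(30, -110, "2014-04-10", 4))
  ssn <- define_season(p, track, breeding, wintering, "spring")
  expect_true(ssn$truncated)
  expect_equal(ssn$termination, max(track$date))
  expect_equal(ssn$onset, as.Date("2014-03-30"))
})

test_that("metric identities hold exactly and days partition the window", {
  sw <- small_world(seed = 9)
  ag <- agent_config()
  tr <- suppressWarnings(simulate_track(ag, sw$fields, sw$config, seed = 4))
  tw <- truth_twilights(tr)
  track <- data.frame(date = tr$date, lat = tr$lat, lon = tr$lon)
  sched <- build_schedule(tw, track, ag$breeding, season = "autumn")
  m <- sched$metrics
  expect_equal(m$total_speed_kmday * m$duration_days, m$total_distance_km,
               tolerance = 1e-12)
  expect_true(all(sched$days$state %in% c("stopover", "travel")))
  expect_equal(nrow(sched$days),
               as.numeric(sched$termination - sched$onset) + 1)
  expect_equal(sum(sched$days$state == "stopover") +
                 sum(sched$days$state == "travel"), nrow(sched$days))
  # total stopover duration equals the in-window stationary days
  expect_equal(m$total_stopover_days, sum(sched$days$state == "stopover"))
})

test_that("adding a stopover day at the same route never raises total speed", {
  days <- data.frame(date = seq(as.Date("2013-09-01"), by = 1, length.out = 5),
                     state = c("travel", "travel", "stopover", "travel", "stopover"),
                     lat = c(50, 48, 48, 46, 46), lon = -100,
                     displacement_km = c(0, 222.4, 0, 222.4, 0))
  ssn <- list(onset = days$date[1], termination = days$date[5], truncated = FALSE)
  m0 <- phenology_metrics(days, ssn)
  extra <- days[3, ]; extra$date <- days$date[5] + 1
  days2 <- rbind(days, extra)
  days2$date <- seq(days$date[1], by = 1, length.out = 6)  # one more rest day
  ssn2 <- list(onset = days2$date[1], termination = days2$date[6], truncated = FALSE)
  m1 <- phenology_metrics(days2, ssn2)
  expect_lt(m1$total_speed_kmday, m0$total_speed_kmday)
})

test_that("travel speed arithmetic is exact", {
  days <- data.frame(date = seq(as.Date("2013-09-01"), by = 1, length.out = 3),
                     state = c("travel", "travel", "stopover"),
                     lat = c(50, 48, 48), lon = c(-100, -100, -100),
                     displacement_km = c(0, 222.4, 0))
  ssn <- list(onset = days$date[1], termination = days$date[3], truncated = FALSE)
  m <- phenology_metrics(days, ssn)
  expect_equal(m$total_distance_km, 222.4)
  expect_equal(m$duration_days, 2)
  expect_equal(m$total_speed_kmday, 111.2)
})

test_that("stopovers are recovered from lightly shaded twilight series", {
  # algorithm validation at light shading (log-normal(0.5, 0.5) delays,
  # median 1.6 min): most multi-day stationary periods are found with
  # boundaries within +-1 day. Under the full fitted twilight model
  # (log-normal(2.2, 1.0)) single nights are not identifiable from twilight
  # shifts; see the acceptance suite and the methods vignette.
  sw <- small_world(seed = 31)
  ag <- agent_config(shading_meanlog = 0.5, shading_sdlog = 0.5)
  found <- 0; total <- 0
  for (s in 1:8) {
    tr <- suppressWarnings(simulate_track(ag, sw$fields, sw$config, seed = 400 + s))
    per <- recovered_periods(tr)
    tp <- truth_periods(tr)
    for (k in seq_len(nrow(tp))) {
      total <- total + 1
      found <- found + any(abs(as.numeric(per$start - tp$start[k])) <= 1 &
                             abs(as.numeric(per$end - tp$end[k])) <= 1)
    }
  }
  expect_gte(found / total, 0.6)
})

test_that("departure days rank high in changepoint score at light shading", {
  sw <- small_world(seed = 31)
  ag <- agent_config(shading_meanlog = 0.5, shading_sdlog = 0.5)
  frac <- c()
  for (s in 1:8) {
    tr <- suppressWarnings(simulate_track(ag, sw$fields, sw$config, seed = 500 + s))
    cp <- changepoint_probabilities(truth_twilights(tr))
    thr <- quantile(cp$score, 0.75)
    dep <- tr$date[tr$state == "travel" &
                     c("x", tr$state[-nrow(tr)]) != "travel"]
    daymax <- tapply(cp$score, cp$date, max)
    frac <- c(frac, mean(daymax[as.character(dep)] > thr, na.rm = TRUE))
  }
  expect_gte(mean(frac), 0.6)
})
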