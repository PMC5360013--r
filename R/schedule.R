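# Migration schedule: changepoint probabilities on twilight series,
# stationary-period segmentation, neighbour merging, season onset and
# termination rules, and phenology metrics.

#' Changepoint probabilities for twilight events
#'
#' For each event, the sunrise and sunset series (handled separately, then
#' interleaved) are tested for a level shift at that event: the two-segment
#' versus one-segment comparison at the minimal segmentation (the event
#' against its immediate same-type predecessor), studentized by a robust
#' (median/MAD) scale of the differenced series so that neither the smooth
#' seasonal drift of twilight times nor the movement steps themselves
#' inflate the null scale. The squared studentized difference is mapped
#' through its null chi-square distribution to a probability. High
#' probability means the event differs from the surrounding events, i.e.
#' the underlying location moved overnight. Wider fixed windows are blind
#' in the study's movement regime, where flights recur every few days and
#' any multi-event window straddles several changepoints.
#'
#' @param tw A `twilight_set`.
#' @param window Minimum number of same-type events required around an
#'   event for its probability to be defined (interface guard; default 6).
#' @return data.frame `date`, `type`, `time`, `prob` (null CDF of the
#'   statistic) and `score` (equivalent continuous log-scale statistic used
#'   by the quantile rule, where `prob` saturates at 1) in event order.
#' @export
changepoint_probabilities <- function(tw, window = 6) {
  use <- tw[tw$flag != "discarded", ]
  for (ty in c("sunrise", "sunset"))
    if (sum(use$type == ty) < max(7, window + 1))
      stop(sprintf("need at least %d %s events", max(7, window + 1), ty))
  out <- data.frame(date = use$date, type = use$type, time = use$time,
                    prob = 0, score = 0)
  for (ty in c("sunrise", "sunset")) {
    sel <- which(use$type == ty)
    tm <- .unwrap_mod(use$time[sel])
    n <- length(sel)
    if (window >= n) stop("window larger than the series")
    d <- diff(tm)
    # remove the seasonal drift of twilight times with a running median:
    # the drift rate depends on latitude, so a global detrend leaves
    # high-latitude residuals that masquerade as movement
    k <- min(2 * (window %/% 2) + 1, length(d) - (1 - length(d) %% 2))
    if (k >= 3) d <- d - stats::runmed(d, k)
    # local robust scale: twilight-time noise and residual drift curvature
    # are heteroscedastic (latitude- and equinox-dependent)
    gl <- 1.4826 * stats::median(abs(d - stats::median(d)))
    k2 <- min(2 * k + 1, length(d) - (1 - length(d) %% 2))
    sc <- if (k2 >= 3) 1.4826 * stats::runmed(abs(d), k2) else rep(gl, length(d))
    sc <- pmax(sc, 0.5 * gl, 1e-6)
    z2 <- (d / sc)^2
    out$prob[sel[-1]] <- stats::pchisq(z2, 1)
    out$score[sel[-1]] <- -stats::pchisq(z2, 1, lower.tail = FALSE,
                                         log.p = TRUE)
  }
  out[order(out$time), ]
}

#' Segment a track into stationary periods and travel days
#'
#' Events whose changepoint probability exceeds the `q` quantile of all
#' probabilities mark movement; a day is a movement day if either of its
#' twilights is marked. Runs of non-movement days lasting at least
#' `min_days` form stationary periods; shorter runs count as travel.
#'
#' @param tw A `twilight_set`.
#' @param track A track data.frame (`date`, `lat`, `lon`) supplying period
#'   mean locations.
#' @param q Quantile threshold in (0, 1), default 0.75.
#' @param min_days Minimum stationary-period duration in days (default 2).
#' @param window Passed to [changepoint_probabilities()].
#' @return data.frame of class `stationary_periods`: `id`, `start`, `end`,
#'   `lat`, `lon`, `duration`, `merged_from`.
#' @export
segment_track <- function(tw, track, q = 0.75, min_days = 2, window = 6) {
  stopifnot(q > 0, q <= 1)
  cp <- changepoint_probabilities(tw, window = window)
  # the quantile rule operates on the continuous log-scale score so that
  # probabilities saturated at 1 still rank
  thr <- stats::quantile(cp$score[is.finite(cp$score)], q, names = FALSE)
  move_dates <- unique(cp$date[cp$score > thr])

  days <- seq(min(track$date), max(track$date), by = "1 day")
  moving <- days %in% move_dates
  r <- rle(!moving)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_days)
  if (!length(keep)) {
    out <- data.frame(id = integer(), start = as.Date(character()),
                      end = as.Date(character()), lat = numeric(),
                      lon = numeric(), duration = numeric(),
                      merged_from = character())
  } else {
    out <- do.call(rbind, lapply(seq_along(keep), function(j) {
      k <- keep[j]
      dd <- days[starts[k]:ends[k]]
      sel <- track$date %in% dd
      data.frame(id = j, start = dd[1], end = dd[length(dd)],
                 lat = mean(track$lat[sel], na.rm = TRUE),
                 lon = mean(track$lon[sel], na.rm = TRUE),
                 duration = length(dd), merged_from = as.character(j))
    }))
  }
  attr(out, "threshold") <- thr
  attr(out, "move_dates") <- sort(move_dates)
  class(out) <- c("stationary_periods", "data.frame")
  out
}

#' Merge nearby consecutive stationary periods
#'
#' Consecutive periods whose mean locations lie within `radius` km
#' (great circle) are merged into one spanning period (mean location
#' duration-weighted), iteratively until a fixed point.
#'
#' @param periods A `stationary_periods` data.frame.
#' @param radius Merge radius, km (default 200).
#' @return The merged `stationary_periods`.
#' @export
merge_neighbours <- function(periods, radius = 200) {
  stopifnot_scalar(radius, "radius", lower = 1e-9)
  p <- periods
  repeat {
    if (nrow(p) < 2) break
    d <- gc_distance_km(p$lat[-nrow(p)], p$lon[-nrow(p)],
                        p$lat[-1], p$lon[-1])
    hit <- which(d <= radius)
    if (!length(hit)) break
    i <- hit[1]
    w <- c(p$duration[i], p$duration[i + 1])
    p$end[i] <- p$end[i + 1]
    p$lat[i] <- sum(w * c(p$lat[i], p$lat[i + 1])) / sum(w)
    p$lon[i] <- sum(w * c(p$lon[i], p$lon[i + 1])) / sum(w)
    p$duration[i] <- sum(w)
    p$merged_from[i] <- paste(p$merged_from[i], p$merged_from[i + 1], sep = ",")
    p <- p[-(i + 1), ]
  }
  p$id <- seq_len(nrow(p))
  rownames(p) <- NULL
  p
}

#' Season onset and termination dates
#'
#' Autumn: onset is the start of the travel run preceding the first
#' stationary site more than `lon_limit` degrees of longitude from the
#' breeding area in the migratory direction; if every stopover lies within
#' that limit, the last day of the travel run following the last such
#' stopover. Termination is the first day of the wintering period (the
#' longest stationary period away from the breeding area). Spring: onset is
#' the first day of the travel run preceding the first stationary period
#' more than `winter_radius` km from the wintering ground; termination is
#' the last day of the last travel run before the breeding area is reached,
#' or, when high-latitude daylight truncates the track, the date of the
#' last estimable location (flagged `truncated`).
#'
#' @param periods Merged `stationary_periods` covering the season.
#' @param track Daily track (`date`, `lat`, `lon`).
#' @param breeding,wintering `c(lat, lon)`; `wintering = NULL` derives it
#'   as the longest stationary period away from breeding.
#' @param season "autumn" or "spring".
#' @param lon_limit Longitude rule for autumn onset, degrees (default 2).
#' @param winter_radius Distance rule for spring onset, km (default 200).
#' @return List: `onset`, `termination` (Dates or NA), `truncated`,
#'   `wintering` (lat/lon used), `reason` (when undefined).
#' @export
define_season <- function(periods, track, breeding, wintering = NULL,
                          season = c("autumn", "spring"),
                          lon_limit = 2, winter_radius = 200) {
  season <- match.arg(season)
  if (nrow(periods) == 0)
    return(list(onset = as.Date(NA), termination = as.Date(NA),
                truncated = FALSE, wintering = wintering,
                reason = "no stationary periods"))
  dist_breed <- gc_distance_km(periods$lat, periods$lon, breeding[1], breeding[2])
  if (is.null(wintering)) {
    away <- which(dist_breed > 500)
    if (!length(away))
      return(list(onset = as.Date(NA), termination = as.Date(NA),
                  truncated = FALSE, wintering = NULL,
                  reason = "no stationary period away from the breeding area"))
    wi <- away[which.max(periods$duration[away])]
    wintering <- c(periods$lat[wi], periods$lon[wi])
  }

  # direction of travel along the longitude axis
  dir <- sign(wrap_lon(wintering[2] - breeding[2]))
  if (dir == 0) dir <- 1
  dlon <- dir * wrap_lon(periods$lon - breeding[2])

  if (season == "autumn") {
    beyond <- which(dlon > lon_limit)
    if (length(beyond)) {
      first_away <- beyond[1]
      # travel run preceding that site: days after the previous period ends
      onset <- if (first_away > 1) periods$end[first_away - 1] + 1
               else track$date[1]
    } else {
      # all stopovers hug the breeding longitude: last day of the travel
      # run following the last of them
      run_start <- periods$end[nrow(periods)] + 1
      later <- track$date[track$date >= run_start]
      onset <- if (length(later)) max(later) else as.Date(NA)
    }
    wint_i <- which(periods$lat == wintering[1] & periods$lon == wintering[2])
    if (!length(wint_i)) {
      d2 <- gc_distance_km(periods$lat, periods$lon, wintering[1], wintering[2])
      wint_i <- which.min(d2)
    }
    termination <- periods$start[wint_i[1]]
    return(list(onset = onset, termination = termination, truncated = FALSE,
                wintering = wintering, reason = NULL))
  }

  # spring
  dist_wint <- gc_distance_km(periods$lat, periods$lon, wintering[1], wintering[2])
  beyond <- which(dist_wint > winter_radius)
  if (!length(beyond))
    return(list(onset = as.Date(NA), termination = as.Date(NA),
                truncated = FALSE, wintering = wintering,
                reason = "no stationary period beyond the wintering radius"))
  first_away <- beyond[1]
  onset <- if (first_away > 1) periods$end[first_away - 1] + 1 else track$date[1]

  arrived <- gc_distance_km(track$lat, track$lon, breeding[1], breeding[2]) < 200
  if (any(arrived)) {
    termination <- min(track$date[arrived])
    truncated <- FALSE
  } else {
    termination <- max(track$date)
    truncated <- TRUE
  }
  list(onset = onset, termination = termination, truncated = truncated,
       wintering = wintering, reason = NULL)
}

#' Assemble a migration schedule with phenology metrics
#'
#' Combines segmentation, merging and the season rules, classifies every
#' day in the migration window as stopover or travel (a partition), and
#' computes the phenology metrics: total migration distance (sum of
#' great-circle legs between consecutive daily locations in the window),
#' duration, total speed of migration (distance / duration, an exact
#' identity), total stopover duration, mean travel speed, and stopover days
#' per 1,000 km.
#'
#' @param tw A `twilight_set`.
#' @param track Daily track (`date`, `lat`, `lon`, ...).
#' @param breeding `c(lat, lon)` of the breeding site.
#' @param wintering Optional `c(lat, lon)`; derived if NULL.
#' @param season "autumn" or "spring".
#' @param q,min_days,window Segmentation parameters.
#' @param merge_radius Merge radius, km.
#' @return A list of class `migration_schedule`: `periods`, `days`
#'   (date/state/lat/lon/displacement), `onset`, `termination`,
#'   `truncated`, `metrics`.
#' @export
build_schedule <- function(tw, track, breeding, wintering = NULL,
                           season = "autumn", q = 0.75, min_days = 2,
                           window = 6, merge_radius = 200) {
  # segment at run length 1, merge nearby fragments (reuniting stationary
  # periods split by a single marked day), then enforce the minimum
  # stopover duration on the merged periods
  periods <- segment_track(tw, track, q = q, min_days = 1, window = window)
  periods <- merge_neighbours(periods, radius = merge_radius)
  periods <- periods[as.numeric(periods$end - periods$start) + 1 >= min_days, ]
  periods$id <- seq_len(nrow(periods))
  rownames(periods) <- NULL
  ssn <- define_season(periods, track, breeding, wintering, season)
  days <- schedule_days(periods, track, ssn$onset, ssn$termination)
  metrics <- phenology_metrics(days, ssn)
  structure(list(periods = periods, days = days, onset = ssn$onset,
                 termination = ssn$termination, truncated = ssn$truncated,
                 wintering = ssn$wintering, metrics = metrics),
            class = "migration_schedule")
}

# classify each day in [onset, termination] as stopover/travel; the two
# classes partition the window
schedule_days <- function(periods, track, onset, termination) {
  if (is.na(onset) || is.na(termination))
    return(data.frame(date = as.Date(character()), state = character(),
                      lat = numeric(), lon = numeric(),
                      displacement_km = numeric()))
  dd <- seq(onset, termination, by = "1 day")
  in_per <- rep(FALSE, length(dd))
  for (p in seq_len(nrow(periods)))
    in_per <- in_per | (dd >= periods$start[p] & dd <= periods$end[p])
  idx <- match(dd, track$date)
  lat <- track$lat[idx]; lon <- track$lon[idx]
  disp <- c(0, gc_distance_km(lat[-length(lat)], lon[-length(lon)],
                              lat[-1], lon[-1]))
  disp[is.na(disp)] <- 0
  data.frame(date = dd, state = ifelse(in_per, "stopover", "travel"),
             lat = lat, lon = lon, displacement_km = disp)
}

#' Phenology metrics for a classified migration window
#'
#' @param days The `days` table of a schedule.
#' @param ssn The season definition (list with `onset`, `termination`,
#'   `truncated`).
#' @return List of metrics; `total_speed * duration == total_distance`
#'   holds exactly.
#' @export
phenology_metrics <- function(days, ssn) {
  if (nrow(days) == 0)
    return(list(total_distance_km = NA_real_, duration_days = NA_real_,
                total_speed_kmday = NA_real_, total_stopover_days = NA_real_,
                mean_travel_speed_kmday = NA_real_,
                stopover_days_per_1000km = NA_real_, truncated = ssn$truncated))
  duration <- as.numeric(ssn$termination - ssn$onset)
  if (duration <= 0) stop("zero-duration migration window")
  total_distance <- sum(days$displacement_km, na.rm = TRUE)
  travel <- days$displacement_km[days$state == "travel"]
  list(total_distance_km = total_distance,
       duration_days = duration,
       total_speed_kmday = total_distance / duration,
       total_stopover_days = sum(days$state == "stopover"),
       mean_travel_speed_kmday = if (length(travel)) mean(travel) else NA_real_,
       stopover_days_per_1000km = sum(days$state == "stopover") /
         (total_distance / 1000),
       truncated = ssn$truncated)
}

#' @export
print.migration_schedule <- function(x, ...) {
  cat(sprintf("<migration_schedule> %d stationary periods, onset %s, termination %s%s\n",
              nrow(x$periods), format(x$onset), format(x$termination),
              if (x$truncated) " [truncated]" else ""))
  if (!is.null(x$metrics$total_speed_kmday) && !is.na(x$metrics$total_speed_kmday))
    cat(sprintf("  total %.0f km in %d days = %.1f km/day; %d stopover days\n",
                x$metrics$total_distance_km, x$metrics$duration_days,
                x$metrics$total_speed_kmday, x$metrics$total_stopover_days))
  invisible(x)
}
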