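# Twilight detection at a fixed light threshold and the outlier edit rule
# (adjust events deviating > 30 min from stable neighbours, discard events
# inside unstable stretches).

#' Read / construct a light series
#'
#' @param time POSIXct (UTC), strictly increasing.
#' @param light Non-negative light intensities (device units or lux).
#' @param device Free-text device tag.
#' @return A data.frame of class `light_series`.
#' @export
light_series <- function(time, light, device = "synthetic") {
  if (is.unsorted(as.numeric(time), strictly = TRUE))
    stop("timestamps must be strictly increasing (no duplicates)")
  if (diff(range(as.numeric(time))) < 86400)
    stop("need at least one full day of data")
  out <- data.frame(time = time, light = light)
  attr(out, "device") <- device
  class(out) <- c("light_series", "data.frame")
  out
}

#' Detect twilight events by threshold crossing
#'
#' Sunrise is an upward crossing of the light threshold, sunset a downward
#' crossing, each linearly interpolated between the bracketing samples.
#' Days without both crossings (polar day/night, gaps) yield no events and
#' are reported in the `days_without_events` attribute; a constant-light
#' series returns an empty set with a diagnostic rather than an error.
#'
#' @param light A `light_series`.
#' @param threshold Light threshold (> 0), default 1.35.
#' @return A data.frame of class `twilight_set` with columns `date` (UTC
#'   date of the event), `type` ("sunrise"/"sunset"), `time` (POSIXct UTC),
#'   `flag` ("kept"), `original_time` (NA).
#' @export
detect_twilights <- function(light, threshold = 1.35) {
  stopifnot_scalar(threshold, "threshold", lower = 1e-12)
  L <- light$light; tt <- light$time
  above <- L > threshold
  if (all(above) || all(!above)) {
    out <- empty_twilight_set()
    attr(out, "diagnostic") <-
      sprintf("no threshold crossings: light %s threshold everywhere (polar %s?)",
              if (all(above)) "above" else "below",
              if (all(above)) "day" else "night")
    attr(out, "days_without_events") <-
      unique(utc_date(tt))
    return(out)
  }
  idx <- which(diff(above) != 0L)
  # linear interpolation between bracketing samples
  frac <- (threshold - L[idx]) / (L[idx + 1L] - L[idx])
  ctime <- tt[idx] + frac * as.numeric(difftime(tt[idx + 1L], tt[idx], units = "secs"))
  type <- ifelse(above[idx + 1L], "sunrise", "sunset")

  out <- data.frame(date = utc_date(ctime), type = type, time = ctime,
                    flag = "kept", original_time = ctime + NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  alldays <- seq(min(utc_date(tt)), max(utc_date(tt)), by = "1 day")
  attr(out, "days_without_events") <- as.Date(setdiff(alldays, out$date),
                                              origin = "1970-01-01")
  attr(out, "threshold") <- threshold
  class(out) <- c("twilight_set", "data.frame")
  out
}

empty_twilight_set <- function() {
  out <- data.frame(date = as.Date(character()), type = character(),
                    time = utc(character()), flag = character(),
                    original_time = utc(character()),
                    stringsAsFactors = FALSE)
  class(out) <- c("twilight_set", "data.frame")
  out
}

# unwrap minutes-of-day of a same-type event series so consecutive values
# never jump across midnight (keeps differences < 12 h)
.unwrap_mod <- function(t) {
  m <- minutes_of_day(t)
  if (length(m) > 1) {
    d <- diff(m)
    step <- cumsum(c(0, -round(d / 1440) * 1440))
    m <- m + step
  }
  m
}

#' Edit twilight events against their neighbours
#'
#' For each kept event, the deviation from the local linear trend of its
#' `window` nearest same-type neighbours (time-of-day space, detrended so
#' fast longitudinal travel does not trigger false flags) is compared with
#' `limit` minutes. Events deviating more than `limit` from stable
#' neighbours (neighbour residual spread `max - min <=` `limit`) are moved
#' onto the trend and flagged `adjusted`; events whose neighbours are
#' themselves unstable are flagged `discarded`. Events at the series ends
#' with fewer than `window` same-type neighbours are kept unflagged.
#' The operation is idempotent.
#'
#' @param tw A `twilight_set`.
#' @param window Number of same-type neighbours examined (default 5,
#'   minimum 3).
#' @param limit Deviation limit in minutes (default 30).
#' @return The edited `twilight_set`; adjusted events retain their original
#'   time in `original_time`. A summary of flag counts is attached as the
#'   `edit_summary` attribute.
#' @export
edit_twilights <- function(tw, window = 5, limit = 30) {
  stopifnot_scalar(limit, "limit", lower = 1e-9)
  if (window < 3) stop("'window' must be at least 3 neighbours")
  out <- tw
  for (ty in c("sunrise", "sunset")) {
    sel <- which(out$type == ty & out$flag != "discarded")
    if (length(sel) < window + 1) next
    tm <- .unwrap_mod(out$time[sel])
    day <- as.numeric(utc_date(out$time[sel]))
    n <- length(sel)
    newflag <- out$flag[sel]
    newtime <- out$time[sel]
    half <- window %/% 2
    for (i in seq_len(n)) {
      # events at the series ends lack a two-sided neighbourhood: keep
      if (i <= half || i > n - half) next
      # `window` nearest same-type neighbours, excluding the event itself
      ord <- order(abs(day - day[i]) + (seq_len(n) == i) * 1e9)
      nb <- sort(ord[seq_len(window)])
      # robust local trend: repeated-median slope over a wider context
      # (2*window+1 nearest events) so an outlier block at the edge of the
      # near window cannot masquerade as drift, median intercept over the
      # near neighbours
      ctx <- sort(ord[seq_len(min(n - 1, 2 * window + 1))])
      dd <- outer(day[ctx], day[ctx], "-")
      dt <- outer(tm[ctx], tm[ctx], "-")
      ratio <- dt / dd
      slope <- stats::median(apply(ratio, 1, function(r)
        stats::median(r[is.finite(r)])), na.rm = TRUE)
      if (!is.finite(slope)) slope <- 0
      intercept <- stats::median(tm[nb] - slope * day[nb])
      pred <- intercept + slope * day[i]
      resid <- tm[nb] - (intercept + slope * day[nb])
      dev <- tm[i] - pred
      stable <- (max(resid) - min(resid)) <= limit
      if (abs(dev) > limit) {
        if (stable) {
          newflag[i] <- "adjusted"
          newtime[i] <- out$time[sel][i] - dev * 60
        } else {
          newflag[i] <- "discarded"
        }
      }
    }
    adj <- sel[newflag != out$flag[sel] & newflag == "adjusted"]
    adj <- adj[is.na(out$original_time[adj])]
    out$original_time[adj] <- out$time[adj]
    out$time[sel] <- newtime
    out$flag[sel] <- newflag
  }
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  attr(out, "edit_summary") <- c(kept = sum(out$flag == "kept"),
                                 adjusted = sum(out$flag == "adjusted"),
                                 discarded = sum(out$flag == "discarded"))
  out
}

#' Pair twilights into days
#'
#' Pairs each kept/adjusted sunrise with the next kept/adjusted sunset
#' closer than 24 h, yielding one row per tag day for the threshold method
#' and the track sampler.
#'
#' @param tw A `twilight_set`.
#' @return data.frame with `date` (UTC date of the pair midpoint),
#'   `rise`, `set` (POSIXct).
#' @export
pair_twilights <- function(tw) {
  use <- tw[tw$flag != "discarded", ]
  rises <- use[use$type == "sunrise", ]
  sets <- use[use$type == "sunset", ]
  out <- NULL
  for (i in seq_len(nrow(rises))) {
    j <- which(as.numeric(sets$time) > as.numeric(rises$time[i]))
    if (!length(j)) next
    j <- j[1]
    dl <- as.numeric(difftime(sets$time[j], rises$time[i], units = "hours"))
    if (dl >= 24) next
    out <- rbind(out, data.frame(rise = rises$time[i], set = sets$time[j]))
  }
  if (is.null(out)) return(data.frame(date = as.Date(character()),
                                      rise = utc(character()),
                                      set = utc(character())))
  mid <- out$rise + as.numeric(difftime(out$set, out$rise, units = "secs")) / 2
  data.frame(date = utc_date(mid), rise = out$rise, set = out$set)
}
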