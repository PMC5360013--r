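# Threshold geolocation and Bayesian track refinement.
#
# Position model: one state (lat, lon) per twilight pair (the midday
# position). The posterior combines
#   * a one-sided log-normal twilight-error model (observed sunrise is late,
#     observed sunset early, by a log-normal shading delay in minutes),
#   * a gamma prior on the great-circle speed between consecutive states,
#   * a land/sea mask weight,
# and is explored by Metropolis-within-Gibbs with Gaussian proposals tuned
# to a 20-40% acceptance rate during burn-in.

#' Threshold-method position from one twilight pair
#'
#' Longitude follows from the observed solar noon (midpoint of sunrise and
#' sunset) against 12:00 UTC corrected by the equation of time; latitude is
#' solved numerically from the observed day length and the solar
#' declination at zenith angle `z0`. Near the equinoxes the day length is
#' nearly independent of latitude and no solution may exist: the latitude
#' is then returned as `NA` with a diagnostic, while the longitude is still
#' valid.
#'
#' @param rise,set POSIXct (UTC) sunrise and sunset of one day.
#' @param z0 Zenith angle defining the twilight events, degrees.
#' @param lat_hint Optional latitude used to disambiguate when the
#'   day-length equation has two roots.
#' @return A list with `lat`, `lon` (degrees; `lat` may be NA), `date`, and
#'   `diagnostic` (NULL or a string).
#' @export
threshold_position <- function(rise, set, z0 = 96.8, lat_hint = NULL) {
  noon <- rise + as.numeric(difftime(set, rise, units = "secs")) / 2
  eph <- solar_ephemeris(noon)
  lon <- wrap_lon((720 - minutes_of_day(noon) - eph$eqtime) / 4)
  obs_daylen <- as.numeric(difftime(set, rise, units = "mins"))
  date <- utc_date(noon)
  diag <- NULL
  lat <- NA_real_

  # refine (lat, lon) so the predicted twilight pair matches the observed
  # one; this removes the midpoint bias that declination drift induces over
  # long days. Latitude from day length (root in phi), longitude from the
  # residual midpoint shift (-4 min per degree east), iterated.
  for (pass in 1:3) {
    f <- function(phi) {
      pr <- twilight_time(date, phi, lon, z0, rise = TRUE)
      ps <- twilight_time(date, phi, lon, z0, rise = FALSE)
      as.numeric(difftime(ps, pr, units = "mins")) - obs_daylen
    }
    grid <- seq(-89.5, 89.5, by = 1)
    fg <- f(grid)
    ok <- is.finite(fg)
    sgn <- which(ok[-1] & ok[-length(fg)] & fg[-1] * fg[-length(fg)] <= 0)
    if (!length(sgn)) {
      return(list(lat = NA_real_, lon = lon, date = date,
                  diagnostic = "day length inconsistent with any latitude at z0 (equinox degeneracy)"))
    }
    roots <- vapply(sgn, function(i)
      stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-6)$root, numeric(1))
    # near the equinox the day-length equation is almost flat in latitude:
    # roots pushed to the polar extremes are artefacts, not positions
    decl <- solar_ephemeris(noon)$declination
    if (all(abs(roots) > 80) && abs(decl) < 8) {
      return(list(lat = NA_real_, lon = lon, date = date,
                  diagnostic = "equinox degeneracy: day length consistent only with artefactual polar latitudes"))
    }
    lat <- if (!is.null(lat_hint)) roots[which.min(abs(roots - lat_hint))]
           else roots[which.min(abs(roots))]
    if (length(roots) > 1)
      diag <- sprintf("two latitude roots (%s); chose %.2f",
                      paste(round(roots, 2), collapse = ", "), lat)
    pr <- twilight_time(date, lat, lon, z0, rise = TRUE)
    ps <- twilight_time(date, lat, lon, z0, rise = FALSE)
    pred_mid <- as.numeric(pr) + as.numeric(difftime(ps, pr, units = "secs")) / 2
    dmid_min <- (as.numeric(noon) - pred_mid) / 60
    if (abs(dmid_min) < 1e-4) break
    lon <- wrap_lon(lon - dmid_min / 4)
  }
  list(lat = lat, lon = lon, date = date, diagnostic = diag)
}

#' Threshold positions for a whole twilight set
#'
#' @param tw A `twilight_set` (or paired twilights from [pair_twilights()]).
#' @param z0 Zenith angle, degrees.
#' @return data.frame `date`, `lat`, `lon`, `rise`, `set` with attribute
#'   `n_unsolvable` counting equinox-degenerate days.
#' @export
threshold_track <- function(tw, z0 = 96.8) {
  pairs <- if (inherits(tw, "twilight_set")) pair_twilights(tw) else tw
  n <- nrow(pairs)
  lat <- lon <- rep(NA_real_, n)
  hint <- NULL
  for (i in seq_len(n)) {
    p <- threshold_position(pairs$rise[i], pairs$set[i], z0, lat_hint = hint)
    lat[i] <- p$lat; lon[i] <- p$lon
    if (!is.na(p$lat)) hint <- p$lat
  }
  out <- data.frame(date = pairs$date, lat = lat, lon = lon,
                    rise = pairs$rise, set = pairs$set)
  attr(out, "n_unsolvable") <- sum(is.na(lat))
  out
}

#' Calibrate zenith angle and the twilight-error model at a known site
#'
#' Twilight errors are one-sided: shading delays the apparent sunrise and
#' advances the apparent sunset, so observed-minus-predicted (sunrise) and
#' predicted-minus-observed (sunset) minutes are positive and modelled
#' log-normal. The zenith angle is estimated so that the smallest observed
#' error equals the expected minimum of the fitted log-normal (two
#' debiasing iterations); this keeps the error sample strictly one-sided so
#' its log-moments estimate `meanlog`/`sdlog`, and reduces exactly to the
#' geometric zenith in the noise-free limit. A near-degenerate error sample
#' (noise-free data) is flagged.
#'
#' @param tw A `twilight_set` recorded at the known site.
#' @param site `c(lat, lon)` of the calibration site, degrees.
#' @param floor_min Error floor in minutes applied before taking logs
#'   (the log-normal is undefined at zero), default 0.1.
#' @param z_range Search range for the zenith angle, degrees.
#' @return A list of class `calibration`: `zenith`, `meanlog`, `sdlog`,
#'   `n`, `degenerate` flag, and the error sample in minutes.
#' @export
calibrate_zenith <- function(tw, site, floor_min = 0.1,
                             z_range = c(85, 105)) {
  use <- tw[tw$flag != "discarded", ]
  if (nrow(use) < 10) stop("need at least 10 twilights at the known site")
  # key every event to its local solar day at the site: a sunset recorded
  # after UTC midnight belongs to the previous local day
  use$date <- utc_date(use$time + 240 * site[2])

  # the zenith search range is clipped to what the site/season can attain:
  # the sun must pass through z0 on every calibration date (between the
  # noon minimum and the midnight maximum of the daily zenith curve)
  dates <- unique(use$date)
  noons <- solar_noon(dates, site[1], site[2])
  z_noon <- solar_zenith(noons, site[1], site[2])
  z_midnight <- solar_zenith(noons + 12 * 3600, site[1], site[2])
  z_lo <- max(z_range[1], max(z_noon) + 0.3)
  z_hi <- min(z_range[2], min(z_midnight) - 0.3)
  if (z_lo >= z_hi)
    stop(sprintf(paste0("the zenith range [%.1f, %.1f] is not attainable at ",
                        "this site in this season (feasible: [%.1f, %.1f])"),
                 z_range[1], z_range[2], max(z_noon), min(z_midnight)))

  errors_at <- function(z0) {
    pred <- twilight_time(use$date, site[1], site[2], z0,
                          rise = use$type == "sunrise")
    e <- as.numeric(difftime(use$time, pred, units = "mins"))
    e[use$type == "sunset"] <- -e[use$type == "sunset"]
    e[!is.na(e)]   # dates where z0 grazes the zenith curve carry no error
  }
  # smallest error is monotone increasing in z0: anchor it at `target`
  solve_z <- function(target) {
    g <- function(z0) min(errors_at(z0)) - target
    glo <- g(z_lo); ghi <- g(z_hi)
    if (glo >= 0) { warning("zenith solution at the lower feasibility bound"); return(z_lo) }
    if (ghi <= 0) { warning("zenith solution at the upper feasibility bound"); return(z_hi) }
    stats::uniroot(g, c(z_lo, z_hi), f.lower = glo, f.upper = ghi, tol = 1e-6)$root
  }

  z0 <- solve_z(0)
  err <- errors_at(z0)
  meanlog <- mean(log(pmax(err, floor_min)))
  sdlog <- stats::sd(log(pmax(err, floor_min)))
  degenerate <- sdlog < 0.05
  if (degenerate) {
    warning("twilight-error sample is degenerate at the floor (noise-free data?); ",
            "log-normal parameters are not informative")
  } else {
    # anchor the minimum error at the median minimum of n log-normal draws,
    # twice, to debias the log-moments
    n <- nrow(use)
    for (k in 1:2) {
      target <- stats::qlnorm(1 - 0.5^(1 / n), meanlog, sdlog)
      z0 <- solve_z(target)
      err <- errors_at(z0)
      meanlog <- mean(log(pmax(err, floor_min)))
      sdlog <- stats::sd(log(pmax(err, floor_min)))
    }
  }
  if (mean(err < -floor_min) > 0.05)
    warning("many negative twilight errors: threshold too low or wrong site?")
  structure(list(zenith = z0, meanlog = meanlog, sdlog = sdlog,
                 n = nrow(use), degenerate = degenerate, errors_min = err),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> zenith %.2f deg, twilight error ~ logN(%.2f, %.2f) min, n = %d%s\n",
              x$zenith, x$meanlog, x$sdlog, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Gamma movement model on inter-twilight speeds
#'
#' Shape < 1 puts the mode at zero: high probability of low speeds, low
#' probability of high speeds. Units are km/h over the great-circle
#' distance between consecutive states.
#'
#' @param shape,rate Gamma parameters (default shape 0.7, rate 0.05, i.e.
#'   scale 20 km/h).
#' @return A list of class `movement_model`.
#' @export
movement_model <- function(shape = 0.7, rate = 0.05) {
  stopifnot_scalar(shape, "shape", lower = 1e-9)
  stopifnot_scalar(rate, "rate", lower = 1e-9)
  structure(list(shape = shape, rate = rate), class = "movement_model")
}

#' Land/sea prior mask
#'
#' Relative (unnormalized) weights; the posterior is invariant to scaling
#' both weights by a common factor.
#'
#' @param fields An [env_fields()] carrying a land raster, or NULL for a
#'   flat mask.
#' @param land_weight,sea_weight Relative weights, `land_weight >=
#'   sea_weight > 0` (default 4:1).
#' @return A list of class `spatial_mask`.
#' @export
spatial_mask <- function(fields = NULL, land_weight = 4, sea_weight = 1) {
  if (sea_weight <= 0 || land_weight < sea_weight)
    stop("need land_weight >= sea_weight > 0")
  structure(list(fields = fields, land_weight = land_weight,
                 sea_weight = sea_weight), class = "spatial_mask")
}

.mask_logw <- function(mask, lat, lon) {
  if (is.null(mask) || is.null(mask$fields))
    return(rep(0, max(length(lat), length(lon))))
  ifelse(is_land(mask$fields, lat, lon), log(mask$land_weight),
         log(mask$sea_weight))
}

# vectorized one-sided twilight log-density for states (lat, lon) on `date`
.twilight_loglik <- function(date, lat, lon, rise_obs, set_obs, calib) {
  pr <- twilight_time(date, lat, lon, calib$zenith, rise = TRUE)
  ps <- twilight_time(date, lat, lon, calib$zenith, rise = FALSE)
  er <- as.numeric(difftime(rise_obs, pr, units = "mins"))
  es <- as.numeric(difftime(ps, set_obs, units = "mins"))
  ll <- stats::dlnorm(er, calib$meanlog, calib$sdlog, log = TRUE) +
    stats::dlnorm(es, calib$meanlog, calib$sdlog, log = TRUE)
  ll[!is.finite(ll)] <- -Inf
  ll[is.na(pr) | is.na(ps)] <- -Inf      # polar: no twilight possible there
  ll
}

#' Bayesian refinement of a twilight track
#'
#' Metropolis-within-Gibbs over per-day midday positions. Odd and even days
#' are updated alternately (each state's full conditional depends only on
#' its two neighbours through the movement prior, so the checkerboard sweep
#' is a valid Gibbs scan and vectorizes). Proposal scales adapt per state
#' during burn-in toward 20-40% acceptance and are then frozen.
#'
#' @param tw A `twilight_set` (or the paired form).
#' @param calib A [calibrate_zenith()] result (or a list with `zenith`,
#'   `meanlog`, `sdlog`).
#' @param move A [movement_model()]; NULL disables the movement prior.
#' @param mask A [spatial_mask()]; NULL for a flat mask.
#' @param n_burn Burn-in sweeps per chain.
#' @param n_iter Post-burn-in sweeps per chain.
#' @param thin Keep every `thin`-th sweep.
#' @param chains Number of chains.
#' @param seed Integer seed.
#' @param init Optional matrix/data.frame of initial `lat`, `lon` per day.
#' @return A list of class `geo_track`: `track` data.frame (date,
#'   lat, lon = posterior medians, lat_sd, lon_sd, rise, set), posterior
#'   `samples` (array draws x day x 2), acceptance rates and a split-chain
#'   R-hat diagnostic per coordinate.
#' @export
refine_track <- function(tw, calib, move = movement_model(),
                         mask = NULL, n_burn = 5000, n_iter = 15000,
                         thin = 5, chains = 2, seed = 1L, init = NULL) {
  pairs <- if (inherits(tw, "twilight_set")) pair_twilights(tw) else tw
  k <- nrow(pairs)
  if (k < 2) stop("need at least 2 twilight pairs")
  set.seed(seed)

  state_time <- pairs$rise + as.numeric(difftime(pairs$set, pairs$rise,
                                                 units = "secs")) / 2
  dt_h <- diff(as.numeric(state_time)) / 3600

  # initial positions: threshold method at an offset zenith so both
  # twilight errors start strictly positive; equinox gaps interpolated
  init_positions <- function(offset) {
    tp <- threshold_track(pairs, z0 = calib$zenith - offset)
    la <- tp$lat; lo <- tp$lon
    if (anyNA(la)) la <- stats::approx(seq_len(k)[!is.na(la)], la[!is.na(la)],
                                       seq_len(k), rule = 2)$y
    if (anyNA(lo)) lo <- stats::approx(seq_len(k)[!is.na(lo)], lo[!is.na(lo)],
                                       seq_len(k), rule = 2)$y
    cbind(la, lo)
  }

  loglik_state <- function(la, lo, idx) {
    ll <- .twilight_loglik(pairs$date[idx], la, lo, pairs$rise[idx],
                           pairs$set[idx], calib) +
      .mask_logw(mask, la, lo)
    ll
  }
  logmove <- function(la1, lo1, la2, lo2, dth) {
    if (is.null(move)) return(rep(0, length(la1)))
    spd <- gc_distance_km(la1, lo1, la2, lo2) / dth
    stats::dgamma(pmax(spd, 1e-12), move$shape, move$rate, log = TRUE)
  }

  keep <- floor(n_iter / thin)
  samples <- array(NA_real_, c(keep * chains, k, 2),
                   dimnames = list(NULL, NULL, c("lat", "lon")))
  acc_all <- numeric(k)

  for (ch in seq_len(chains)) {
    if (!is.null(init)) {
      cur <- as.matrix(init)[, 1:2, drop = FALSE]
    } else {
      cur <- NULL
      for (offset in c(0.6, 1.2, 2.5)) {
        cand <- init_positions(offset)
        ll <- loglik_state(cand[, 1], cand[, 2], seq_len(k))
        if (all(is.finite(ll))) { cur <- cand; break }
        # keep the best candidate; non-finite states get nudged below
        if (is.null(cur)) cur <- cand
      }
      ll <- loglik_state(cur[, 1], cur[, 2], seq_len(k))
      bad <- which(!is.finite(ll))
      for (i in bad) {   # local jitter search
        ok <- FALSE
        for (tryi in 1:200) {
          cand <- cur[i, ] + stats::rnorm(2, 0, 1.5)
          cand[1] <- max(min(cand[1], 89), -89)
          if (is.finite(loglik_state(cand[1], cand[2], i))) {
            cur[i, ] <- cand; ok <- TRUE; break
          }
        }
        if (!ok) stop("could not find a finite-posterior initialization for day ", i)
      }
    }

    prop_sd <- rep(1, k)
    acc <- att <- rep(0, k)
    ll_cur <- loglik_state(cur[, 1], cur[, 2], seq_len(k))

    total <- n_burn + n_iter
    kept_i <- 0L
    for (it in seq_len(total)) {
      for (par in 0:1) {
        idx <- seq_len(k)[seq_len(k) %% 2 == par]
        la_p <- cur[idx, 1] + stats::rnorm(length(idx), 0, prop_sd[idx])
        lo_p <- cur[idx, 2] + stats::rnorm(length(idx), 0, prop_sd[idx])
        la_p <- pmax(pmin(la_p, 89.5), -89.5)

        ll_p <- loglik_state(la_p, lo_p, idx)
        dlp <- ll_p - ll_cur[idx]
        prev <- idx - 1L; nxt <- idx + 1L
        hasp <- prev >= 1L; hasn <- nxt <= k
        if (any(hasp)) {
          i2 <- idx[hasp]
          dlp[hasp] <- dlp[hasp] +
            logmove(cur[i2 - 1, 1], cur[i2 - 1, 2], la_p[hasp], lo_p[hasp], dt_h[i2 - 1]) -
            logmove(cur[i2 - 1, 1], cur[i2 - 1, 2], cur[i2, 1], cur[i2, 2], dt_h[i2 - 1])
        }
        if (any(hasn)) {
          i2 <- idx[hasn]
          dlp[hasn] <- dlp[hasn] +
            logmove(la_p[hasn], lo_p[hasn], cur[i2 + 1, 1], cur[i2 + 1, 2], dt_h[i2]) -
            logmove(cur[i2, 1], cur[i2, 2], cur[i2 + 1, 1], cur[i2 + 1, 2], dt_h[i2])
        }
        take <- !is.na(dlp) & (log(stats::runif(length(idx))) < dlp)
        if (any(take)) {
          ti <- idx[take]
          cur[ti, 1] <- la_p[take]; cur[ti, 2] <- lo_p[take]
          ll_cur[ti] <- ll_p[take]
        }
        att[idx] <- att[idx] + 1
        acc[idx] <- acc[idx] + take
      }
      if (it <= n_burn && it %% 50 == 0) {
        rate <- acc / pmax(att, 1)
        prop_sd <- prop_sd * exp(0.5 * (rate - 0.3))
        prop_sd <- pmin(pmax(prop_sd, 0.02), 10)
        acc[] <- 0; att[] <- 0
      }
      if (it == n_burn) { acc[] <- 0; att[] <- 0 }
      if (it > n_burn && (it - n_burn) %% thin == 0) {
        kept_i <- kept_i + 1L
        samples[(ch - 1L) * keep + kept_i, , 1] <- cur[, 1]
        samples[(ch - 1L) * keep + kept_i, , 2] <- cur[, 2]
      }
    }
    acc_all <- acc_all + acc / pmax(att, 1) / chains
  }

  med <- apply(samples, c(2, 3), stats::median)
  sds <- apply(samples, c(2, 3), stats::sd)
  track <- data.frame(date = pairs$date, lat = med[, 1], lon = med[, 2],
                      lat_sd = sds[, 1], lon_sd = sds[, 2],
                      rise = pairs$rise, set = pairs$set)

  rhat <- NULL
  if (chains >= 2) {
    rhat <- sapply(1:2, function(cc) {
      sapply(seq_len(k), function(i) {
        draws <- matrix(samples[, i, cc], ncol = chains)
        w <- mean(apply(draws, 2, stats::var))
        b <- stats::var(colMeans(draws)) * nrow(draws)
        if (w <= 0) return(1)
        sqrt(((nrow(draws) - 1) / nrow(draws) * w + b / nrow(draws)) / w)
      })
    })
    colnames(rhat) <- c("lat", "lon")
  }
  structure(list(track = track, samples = samples, acceptance = acc_all,
                 rhat = rhat, calib = calib),
            class = "geo_track")
}

#' Fill missing days of a track by interpolation
#'
#' Days without a usable twilight pair (edited out, discarded, equinox) get
#' positions interpolated linearly in time between neighbouring estimates,
#' twilight times predicted from the interpolated position at the given
#' zenith angle, and a conservative latitude SD (the largest observed SD).
#' Filled rows are flagged in the `filled` column.
#'
#' @param track A track data.frame (`date`, `lat`, `lon`, `lat_sd`,
#'   `lon_sd`, `rise`/`sunrise`, `set`/`sunset`).
#' @param zenith Zenith angle for predicted twilights of filled days.
#' @return The track completed to a daily sequence.
#' @export
fill_track_days <- function(track, zenith = 96.8) {
  rise_col <- if ("sunrise" %in% names(track)) "sunrise" else "rise"
  set_col <- if ("sunset" %in% names(track)) "sunset" else "set"
  days <- seq(min(track$date), max(track$date), by = "1 day")
  idx <- match(days, track$date)
  out <- track[idx, ]
  out$date <- days
  out$filled <- is.na(idx)
  if (!any(out$filled)) { rownames(out) <- NULL; return(out) }
  t0 <- as.numeric(days)
  known <- !out$filled
  out$lat <- stats::approx(t0[known], track$lat[match(days[known], track$date)],
                           t0, rule = 2)$y
  out$lon <- stats::approx(t0[known], track$lon[match(days[known], track$date)],
                           t0, rule = 2)$y
  fsd <- max(track$lat_sd, na.rm = TRUE)
  out$lat_sd[out$filled] <- fsd
  if ("lon_sd" %in% names(out)) out$lon_sd[out$filled] <- max(track$lon_sd, na.rm = TRUE)
  fill <- which(out$filled)
  out[[rise_col]][fill] <- twilight_time(out$date[fill], out$lat[fill],
                                         out$lon[fill], zenith, rise = TRUE)
  out[[set_col]][fill] <- twilight_time(out$date[fill], out$lat[fill],
                                        out$lon[fill], zenith, rise = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.geo_track <- function(x, ...) {
  cat(sprintf("<geo_track> %d days, mean acceptance %.2f, max R-hat %.3f\n",
              nrow(x$track), mean(x$acceptance),
              if (is.null(x$rhat)) NA else max(x$rhat)))
  invisible(x)
}
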