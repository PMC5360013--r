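# End-to-end pipeline driver: simulate (optional) -> twilight -> geolocate
# -> schedule -> annotate -> fit, with every intermediate product written to
# an artifact directory and a provenance file sufficient to re-run
# bit-identically.

#' Pipeline configuration
#'
#' Defaults are the analysis constants of the study design: light threshold
#' 1.35, twilight edit limit 30 min, changepoint quantile 0.75, minimum
#' stopover 2 days, merge radius 200 km, airspeed 13 m/s, movement model
#' gamma(0.7, rate 0.05), land:sea mask weights 4:1.
#'
#' @param threshold Light threshold.
#' @param zenith Zenith override (NULL = calibrate from the breeding-site
#'   segment of the data).
#' @param edit_limit Twilight edit limit, minutes.
#' @param edit_window Neighbour window for twilight editing.
#' @param cp_quantile Changepoint quantile.
#' @param cp_window Changepoint window (same-type events).
#' @param min_stopover Minimum stopover length, days.
#' @param merge_radius Stationary-period merge radius, km.
#' @param airspeed Airspeed for flow assistance, m/s.
#' @param move_shape,move_rate Movement-model gamma parameters (km/h).
#' @param land_weight,sea_weight Mask weights.
#' @param mcmc List: n_burn, n_iter, thin, chains.
#' @param seed Integer seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 1.35, zenith = NULL,
                            edit_limit = 30, edit_window = 5,
                            cp_quantile = 0.75, cp_window = 6,
                            min_stopover = 2, merge_radius = 200,
                            airspeed = 13,
                            move_shape = 0.7, move_rate = 0.05,
                            land_weight = 4, sea_weight = 1,
                            mcmc = list(n_burn = 2000, n_iter = 6000,
                                        thin = 3, chains = 2),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on one bird
#'
#' Stages: twilight detection at the fixed threshold, neighbour editing,
#' zenith/twilight-error calibration at the known deployment site (using
#' the leading stationary segment), Bayesian track refinement, changepoint
#' segmentation into a schedule, environmental annotation into a bird-day
#' table. Each stage's product is written to `out_dir` when given, plus a
#' provenance JSON with the full configuration and seed.
#'
#' @param light A `light_series`.
#' @param fields An [env_fields()] covering the track.
#' @param breeding `c(lat, lon)` deployment site (calibration site).
#' @param wintering Optional known `c(lat, lon)` destination; derived from
#'   the schedule when NULL.
#' @param config A [pipeline_config()].
#' @param calib_days Number of leading days treated as recorded at the
#'   breeding site for calibration (default 10).
#' @param calib Optional precomputed [calibrate_zenith()] result (e.g. from
#'   a separate stationary recording at the deployment site, or pooled
#'   across individuals); when given, the calibration stage is skipped.
#' @param season "autumn" or "spring".
#' @param bird_id,year Identifiers for the bird-day table.
#' @param out_dir Optional artifact directory.
#' @return List of class `pipeline_result` with all stage products.
#' @export
run_pipeline <- function(light, fields, breeding, wintering = NULL,
                         config = pipeline_config(), calib_days = 10,
                         calib = NULL, season = "autumn", bird_id = "bird1",
                         year = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  tw <- stage("twilight", {
    tw0 <- detect_twilights(light, threshold = config$threshold)
    edit_twilights(tw0, window = config$edit_window, limit = config$edit_limit)
  })

  if (is.null(calib)) calib <- stage("calibrate", {
    cal_tw <- tw[tw$date <= min(tw$date) + calib_days, ]
    if (!is.null(config$zenith)) {
      cc <- tryCatch(calibrate_zenith(cal_tw, breeding),
                     warning = function(w) suppressWarnings(calibrate_zenith(cal_tw, breeding)))
      cc$zenith <- config$zenith
      cc
    } else calibrate_zenith(cal_tw, breeding)
  })

  geo <- stage("geolocate", refine_track(
    tw, calib,
    move = movement_model(config$move_shape, config$move_rate),
    mask = spatial_mask(fields, config$land_weight, config$sea_weight),
    n_burn = config$mcmc$n_burn, n_iter = config$mcmc$n_iter,
    thin = config$mcmc$thin, chains = config$mcmc$chains,
    seed = config$seed))
  track <- geo$track
  names(track)[names(track) == "rise"] <- "sunrise"
  names(track)[names(track) == "set"] <- "sunset"
  track <- fill_track_days(track, zenith = calib$zenith)

  sched <- stage("schedule", build_schedule(
    tw, track, breeding, wintering, season = season, q = config$cp_quantile,
    min_days = config$min_stopover, window = config$cp_window,
    merge_radius = config$merge_radius))

  destination <- if (season == "autumn") (wintering %||% sched$wintering)
                 else breeding
  bird_days <- stage("annotate", build_bird_day_table(
    sched, track, fields, destination, bird_id = bird_id, year = year,
    airspeed = config$airspeed))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_twilights_csv(tw, file.path(out_dir, "twilights.csv"))
    write_track_csv(track, file.path(out_dir, "track.csv"))
    write_track_geojson(track, file.path(out_dir, "track.geojson"))
    write_bird_days_csv(bird_days, file.path(out_dir, "bird_days.csv"))
    prov <- c(config, list(calib_zenith = calib$zenith,
                           calib_meanlog = calib$meanlog,
                           calib_sdlog = calib$sdlog,
                           breeding = breeding,
                           wintering = destination,
                           season = season, bird_id = bird_id,
                           package_version = as.character(utils::packageVersion("wheatrack"))))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }

  structure(list(twilights = tw, calibration = calib, geo = geo,
                 track = track, schedule = sched, bird_days = bird_days,
                 config = config),
            class = "pipeline_result")
}

#' Fit the standard departure and travel-speed models to a bird-day table
#'
#' Convenience wrapper reproducing the reaction-norm model structure:
#' z-transforms the sunset covariates, screens them for collinearity
#' (VIF < 2), fits the departure MELR on stopover rows and the weighted
#' travel-speed LMM (log10 response, weights = inverse latitude SD) on
#' travel rows, and simulates the posteriors.
#'
#' @param bird_days A `bird_day_table` (rows from one or more birds).
#' @param n_draws Posterior draws.
#' @param seed Integer seed.
#' @param vif_threshold Collinearity threshold (default 2).
#' @return List with `departure` and `travel_speed` entries (`fit`, `cri`,
#'   `r2`), plus the VIF report.
#' @export
fit_reaction_norms <- function(bird_days, n_draws = 2000, seed = 1L,
                               vif_threshold = 2) {
  covs <- c("temperature", "precipitation", "pressure", "wind_speed",
            "flow_assistance", "remaining_distance")
  df <- as.data.frame(bird_days)
  df <- df[!df$flow_missing, ]
  n_flow_dropped <- sum(bird_days$flow_missing)

  vif <- vif_screen(df, covs, threshold = vif_threshold)
  keep <- vif$retained
  zdf <- z_transform(df, keep)
  inter <- if ("remaining_distance" %in% keep)
    setdiff(keep, "remaining_distance") else character()

  stop_rows <- zdf[zdf$day_type == "stopover" & !is.na(zdf$departure), ]
  dep_spec <- model_spec("departure", fixed = keep, interactions = inter,
                         family = "binomial")
  dep_fit <- fit_melr(stop_rows, dep_spec)
  dep_cri <- posterior_sim(dep_fit, n = n_draws, seed = seed)

  travel_rows <- zdf[zdf$day_type == "travel" & !is.na(zdf$travel_speed) &
                       zdf$travel_speed > 0, ]
  travel_rows$w_inv_latsd <- 1 / pmax(travel_rows$lat_sd, 1e-6)
  spd_spec <- model_spec("travel_speed", transform = "log10", fixed = keep,
                         interactions = inter, weights = "w_inv_latsd",
                         family = "gaussian")
  spd_fit <- fit_lmm(travel_rows, spd_spec)
  spd_cri <- posterior_sim(spd_fit, n = n_draws, seed = seed + 1L)

  list(departure = list(fit = dep_fit, cri = dep_cri, r2 = r_squared(dep_fit)),
       travel_speed = list(fit = spd_fit, cri = spd_cri, r2 = r_squared(spd_fit)),
       vif = vif, n_flow_dropped = n_flow_dropped)
}

#' Total-speed-of-migration models
#'
#' Two weighted linear mixed models across migrations (log10 response and
#' log10 predictor, individual as the random factor): total speed of
#' migration against total stopover duration, and against mean travel
#' speed plus season.
#'
#' @param migrations data.frame with one row per bird-season: `bird`,
#'   `season`, `total_speed`, `total_stopover_days`, `mean_travel_speed`.
#' @param n_draws,seed Posterior simulation settings.
#' @return List of two fits with CrI tables.
#' @export
fit_total_speed_models <- function(migrations, n_draws = 2000, seed = 1L) {
  df <- migrations
  df$log_stopover <- log10(pmax(df$total_stopover_days, 0.5))
  df$log_travel <- log10(df$mean_travel_speed)
  df$season_num <- as.numeric(factor(df$season)) - 1

  m1 <- fit_lmm(df, model_spec("total_speed", transform = "log10",
                               fixed = "log_stopover", moderator = "log_stopover",
                               random = "bird", family = "gaussian"))
  m2 <- fit_lmm(df, model_spec("total_speed", transform = "log10",
                               fixed = c("log_travel", "season_num"),
                               moderator = "log_travel",
                               random = "bird", family = "gaussian"))
  list(stopover = list(fit = m1, cri = posterior_sim(m1, n_draws, seed)),
       travel = list(fit = m2, cri = posterior_sim(m2, n_draws, seed + 1L)))
}
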