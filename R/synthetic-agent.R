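# Agent-based truth generator: a nocturnal migrant whose evening departure
# decisions follow a known logistic model on z-scored sunset covariates and
# whose nightly flight distances follow a known log10-linear model, moving
# along the great circle toward its destination. The resulting per-day truth
# table (locations, states, covariates, true and shaded twilight times) is
# the reference for every recovery test.

#' Agent configuration for the migration simulator
#'
#' Coefficient defaults reproduce the structure and magnitudes of the
#' fitted departure-probability and travel-speed models for the study
#' system: departure probability is logistic in z-scored sunset covariates
#' with interactions against remaining migration distance; nightly flight
#' distance is log10-linear in the same covariates.
#'
#' @param breeding,wintering `c(lat, lon)` of the two season endpoints,
#'   degrees.
#' @param beta Named departure coefficients on the z-scale: `intercept`,
#'   main effects `temperature`, `precipitation`, `pressure`, `wind_speed`,
#'   `flow_assistance`, `remaining_distance`, and interactions named
#'   `<covariate>:remaining_distance`.
#' @param gamma Named flight-distance coefficients (same naming), response
#'   log10(km/night).
#' @param gamma_sd Residual SD of log10 nightly distance.
#' @param airspeed Airspeed used for flow assistance, m/s (> 0).
#' @param ground_speed Ground speed used to cap nightly distance, km/h.
#' @param max_flight_h Maximum flight hours per night.
#' @param shading_meanlog,shading_sdlog Log-normal twilight shading delay
#'   parameters (minutes); `shading_sdlog` must be > 0 unless shading is
#'   disabled with `shading = FALSE`.
#' @param shading Logical; FALSE gives the noise-free limit (zero delays).
#' @param zenith Zenith angle at which the tag's light threshold is crossed,
#'   degrees.
#' @param season_start First date of the simulation.
#' @param scaling Named list of `c(mean, sd)` reference scalings used to
#'   z-score raw covariates inside the simulator (the truth table stores
#'   both raw and z-scored values).
#' @param arrival_radius_km Distance at which the destination counts as
#'   reached.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(breeding = c(65.6, -145.4),
                         wintering = c(12, -95),
                         beta = c(intercept = -0.25,
                                  temperature = -0.30,
                                  precipitation = 0.14,
                                  pressure = -0.09,
                                  wind_speed = 0.00,
                                  flow_assistance = -0.33,
                                  remaining_distance = 0.98,
                                  "temperature:remaining_distance" = -0.83,
                                  "precipitation:remaining_distance" = 0.07,
                                  "pressure:remaining_distance" = -0.30,
                                  "wind_speed:remaining_distance" = 0.20,
                                  "flow_assistance:remaining_distance" = 0.06),
                         gamma = c(intercept = 2.45,
                                   temperature = -0.12,
                                   precipitation = -0.01,
                                   pressure = 0.08,
                                   wind_speed = 0.00,
                                   flow_assistance = -0.04,
                                   remaining_distance = -0.16,
                                   "temperature:remaining_distance" = -0.06),
                         gamma_sd = 0.30,
                         airspeed = 13, ground_speed = 50, max_flight_h = 10,
                         shading_meanlog = 2.2, shading_sdlog = 1.0,
                         shading = TRUE,
                         zenith = 96.8,
                         season_start = as.Date("2013-08-08"),
                         scaling = list(temperature = c(14, 6),
                                        precipitation = c(2e-4, 3e-4),
                                        pressure = c(1010, 6),
                                        wind_speed = c(3.5, 1.8),
                                        flow_assistance = c(2, 4),
                                        remaining_distance = c(3300, 2600)),
                         arrival_radius_km = 50) {
  stopifnot_scalar(airspeed, "airspeed", lower = 1e-9)
  if (shading) stopifnot_scalar(shading_sdlog, "shading_sdlog", lower = 1e-9)
  if (is.na(beta["intercept"])) stop("'beta' needs an 'intercept'")
  structure(list(breeding = breeding, wintering = wintering, beta = beta,
                 gamma = gamma, gamma_sd = gamma_sd, airspeed = airspeed,
                 ground_speed = ground_speed, max_flight_h = max_flight_h,
                 shading_meanlog = shading_meanlog,
                 shading_sdlog = shading_sdlog, shading = shading,
                 zenith = zenith, season_start = as.Date(season_start),
                 scaling = scaling, arrival_radius_km = arrival_radius_km),
            class = "agent_config")
}

# z-score a named covariate against the agent's reference scaling
.agent_z <- function(agent, name, value) {
  sc <- agent$scaling[[name]]
  (value - sc[1]) / sc[2]
}

# linear predictor from named coefficients and named z-scored covariates
.agent_lp <- function(coefs, zc) {
  lp <- unname(coefs["intercept"])
  for (nm in names(coefs)) {
    if (nm == "intercept") next
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      lp <- lp + coefs[[nm]] * zc[[parts[1]]] * zc[[parts[2]]]
    } else lp <- lp + coefs[[nm]] * zc[[nm]]
  }
  unname(lp)
}

#' Simulate a migratory track with known behavioural coefficients
#'
#' Each evening the bird evaluates its sunset covariates (weather
#' interpolated at its location, best flow assistance toward the
#' destination, remaining great-circle distance), z-scores them against the
#' agent's reference scaling, and departs with probability
#' `plogis(beta . x)`. On flight nights the distance covered is
#' `10^(gamma . x + N(0, gamma_sd))` km, capped at
#' `max_flight_h * ground_speed`, along the great circle toward the
#' destination. The simulation ends at the date-span end; arrival at the
#' destination turns all later days into stationary days there.
#'
#' Day classification follows the tag's perspective: day `d` is a travel day
#' when the bird flew the night into it, so travel days have positive
#' overnight displacement and stopover days zero. The departure indicator is
#' defined on stopover days and equals 1 on the last evening of a stopover.
#'
#' @param agent An [agent_config()].
#' @param weather An [env_fields()] covering the span.
#' @param world The [world_config()] used to build `weather` (supplies the
#'   date span and seed offset).
#' @param seed Integer seed for the behavioural and shading draws.
#' @return A data.frame of class `truth_record`: per-day date, true
#'   location, state, departure indicator, displacement, raw and z-scored
#'   sunset covariates, true and shaded twilight times, and flags. The
#'   attribute `arrived` reports whether the destination was reached;
#'   a truncated track carries `truncated = TRUE` and a warning is issued.
#' @export
simulate_track <- function(agent, weather, world, seed = world$seed + 1L) {
  stopifnot(inherits(agent, "agent_config"), inherits(weather, "env_fields"))
  set.seed(seed)
  dates <- seq(max(agent$season_start, world$start), world$end, by = "1 day")
  nmax <- length(dates)
  covnames <- c("temperature", "precipitation", "pressure", "wind_speed",
                "flow_assistance", "remaining_distance")

  lat <- numeric(nmax); lon <- numeric(nmax)
  flew <- logical(nmax); pdep <- rep(NA_real_, nmax)
  polar <- logical(nmax); arrived_on <- NA_integer_
  raw <- matrix(NA_real_, nmax, length(covnames),
                dimnames = list(NULL, covnames))
  zsc <- raw
  rise_true <- set_true <- rep(utc("1970-01-01 00:00:00"), nmax)
  d_rise <- d_set <- numeric(nmax)

  lat[1] <- agent$breeding[1]; lon[1] <- agent$breeding[2]
  for (d in seq_len(nmax)) {
    if (d > 1) {
      if (flew[d - 1] && is.na(arrived_on)) {
        # position advanced overnight (computed at decision time below)
      } else {
        lat[d] <- lat[d - 1]; lon[d] <- lon[d - 1]
      }
    }
    rs <- twilight_time(dates[d], lat[d], lon[d], agent$zenith, rise = TRUE)
    ss <- twilight_time(dates[d], lat[d], lon[d], agent$zenith, rise = FALSE)
    polar[d] <- is.na(rs) || is.na(ss)
    if (!polar[d]) {
      rise_true[d] <- rs; set_true[d] <- ss
      if (agent$shading) {
        d_rise[d] <- stats::rlnorm(1, agent$shading_meanlog, agent$shading_sdlog)
        d_set[d] <- stats::rlnorm(1, agent$shading_meanlog, agent$shading_sdlog)
      }
    } else {
      rise_true[d] <- NA; set_true[d] <- NA
    }

    remaining <- gc_distance_km(lat[d], lon[d],
                                agent$wintering[1], agent$wintering[2])
    if (is.na(arrived_on) && remaining <= agent$arrival_radius_km)
      arrived_on <- d

    # sunset covariates (use solar sunset even on polar-flagged days when
    # possible; otherwise local midnight-sun noon + 12 h as a stand-in time)
    tcov <- if (!polar[d]) set_true[d] else solar_noon(dates[d], lat[d], lon[d]) + 6 * 3600
    cv <- c(
      temperature = interp_field(weather, "temp", tcov, lat[d], lon[d]),
      precipitation = precip_window(weather, tcov, lat[d], lon[d]),
      pressure = interp_field(weather, "sp", tcov, lat[d], lon[d]),
      wind_speed = NA_real_, flow_assistance = NA_real_,
      remaining_distance = remaining)
    u <- interp_field(weather, "u_sfc", tcov, lat[d], lon[d])
    v <- interp_field(weather, "v_sfc", tcov, lat[d], lon[d])
    cv["wind_speed"] <- sqrt(u^2 + v^2)
    cv["flow_assistance"] <- if (remaining > 1e-6)
      best_flow(weather, tcov, lat[d], lon[d], agent$wintering[1],
                agent$wintering[2], z = agent$airspeed) else NA_real_
    raw[d, ] <- cv
    for (nm in covnames) zsc[d, nm] <- .agent_z(agent, nm, cv[[nm]])

    # evening decision (no flights once arrived; flow NA blocks the model,
    # treat as staying put that night)
    if (is.na(arrived_on) && d < nmax && !anyNA(zsc[d, ])) {
      zl <- as.list(zsc[d, ])
      pdep[d] <- stats::plogis(.agent_lp(agent$beta, zl))
      flew[d] <- stats::runif(1) < pdep[d]
      if (flew[d]) {
        dist <- 10^(.agent_lp(agent$gamma, zl) +
                      stats::rnorm(1, 0, agent$gamma_sd))
        dist <- min(dist, agent$max_flight_h * agent$ground_speed, remaining)
        brg <- gc_bearing(lat[d], lon[d], agent$wintering[1], agent$wintering[2])
        nxt <- gc_destination(lat[d], lon[d], brg, dist)
        lat[d + 1] <- nxt$lat; lon[d + 1] <- nxt$lon
      }
    }
  }

  state <- c("stopover", ifelse(flew[-nmax], "travel", "stopover"))
  displacement <- c(0, gc_distance_km(lat[-nmax], lon[-nmax], lat[-1], lon[-1]))
  departure <- ifelse(state == "stopover", as.integer(flew), NA_integer_)

  out <- data.frame(date = dates, lat = lat, lon = lon, state = state,
                    departure = departure, displacement_km = displacement,
                    p_depart = pdep, polar = polar,
                    stringsAsFactors = FALSE)
  for (nm in covnames) out[[nm]] <- raw[, nm]
  for (nm in covnames) out[[paste0("z_", nm)]] <- zsc[, nm]
  out$rise_true <- rise_true; out$set_true <- set_true
  out$rise_delay_min <- d_rise; out$set_delay_min <- d_set
  out$rise_shaded <- rise_true + 60 * d_rise
  out$set_shaded <- set_true - 60 * d_set

  attr(out, "arrived") <- !is.na(arrived_on)
  attr(out, "truncated") <- is.na(arrived_on)
  if (is.na(arrived_on))
    warning("destination not reached within the date span; track truncated")
  class(out) <- c("truth_record", "data.frame")
  out
}

#' Simulate an archival light series from a truth track
#'
#' Light is a logistic function of solar zenith angle calibrated so that the
#' detection threshold is crossed exactly at the agent's configured zenith
#' angle, making the threshold method exactly invertible in the noise-free
#' limit. Per-twilight shading delays (already drawn into the truth record)
#' shift the morning limb later and the evening limb earlier by warping the
#' time at which the zenith is evaluated, so apparent sunrise is never
#' earlier than true sunrise and apparent sunset never later than true
#' sunset. Polar days are emitted with light above the threshold throughout
#' and flagged.
#'
#' @param truth A `truth_record` from [simulate_track()].
#' @param agent The [agent_config()] used to generate it.
#' @param cadence_min Logger sampling cadence, minutes (default 5, typical
#'   archival-tag resolution; bounds twilight discretization error at half
#'   the cadence).
#' @param light_max Saturated daytime light value (device units).
#' @param threshold Light threshold the calibration targets (default 1.35).
#' @param width Logistic width in degrees of zenith.
#' @return A data.frame of class `light_series` with columns `time`
#'   (POSIXct UTC) and `light`; attribute `polar_days` lists flagged dates.
#' @export
simulate_light <- function(truth, agent, cadence_min = 5, light_max = 64,
                           threshold = 1.35, width = 1) {
  stopifnot(inherits(truth, "truth_record"))
  n <- nrow(truth)
  noons <- solar_noon(truth$date, truth$lat, truth$lon)
  t0 <- noons[1] - 12 * 3600
  t1 <- noons[n] + 12 * 3600
  tt <- seq(t0, t1, by = cadence_min * 60)
  # assign each sample to a truth day by nearest local solar noon
  bounds <- (as.numeric(noons[-n]) + as.numeric(noons[-1])) / 2
  day <- findInterval(as.numeric(tt), bounds) + 1L

  offset <- stats::qlogis(threshold / light_max)
  lat <- truth$lat[day]; lon <- truth$lon[day]
  warp <- numeric(length(tt))
  morning <- as.numeric(tt) < as.numeric(noons[day])
  warp[morning] <- -60 * truth$rise_delay_min[day][morning]
  warp[!morning] <- 60 * truth$set_delay_min[day][!morning]
  z <- solar_zenith(tt + warp, lat, lon)
  light <- light_max * stats::plogis((agent$zenith - z) / width + offset)
  light[truth$polar[day]] <- light_max   # midnight sun: sensor saturated

  out <- data.frame(time = tt, light = light)
  attr(out, "polar_days") <- truth$date[truth$polar]
  attr(out, "cadence_min") <- cadence_min
  class(out) <- c("light_series", "data.frame")
  out
}
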