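# Interchange formats: light TSV, twilight CSV, track CSV/GeoJSON, gridded
# weather as a self-describing text format (JSON header + long CSV), bird-day
# CSV and fit JSON. All times ISO-8601 UTC; all round-trips lossless.

.ISO <- "%Y-%m-%dT%H:%M:%OS3Z"

fmt_time <- function(t) format(t, .ISO, tz = "UTC")
parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")

#' Write / read a light series (2-column TSV)
#'
#' @param x A `light_series`.
#' @param path File path.
#' @return `read_light_tsv` returns a `light_series`.
#' @export
write_light_tsv <- function(x, path) {
  utils::write.table(data.frame(time = fmt_time(x$time), light = x$light),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_light_tsv
#' @export
read_light_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "light") %in% names(df)))
    stop("light TSV must have columns 'time' and 'light'")
  tt <- parse_time(df$time)
  if (anyNA(tt)) stop(sprintf("unparseable timestamp at row %d",
                              which(is.na(tt))[1]))
  light_series(tt, df$light, device = "file")
}

#' Write / read a twilight set (CSV)
#'
#' @param tw A `twilight_set`.
#' @param path File path.
#' @export
write_twilights_csv <- function(tw, path) {
  utils::write.csv(data.frame(date = format(tw$date), type = tw$type,
                              time = fmt_time(tw$time), flag = tw$flag,
                              original_time = ifelse(is.na(tw$original_time), "",
                                                     fmt_time(tw$original_time))),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_twilights_csv
#' @export
read_twilights_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "type", "time", "flag", "original_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("twilight CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(date = as.Date(df$date), type = df$type,
                    time = parse_time(df$time), flag = df$flag,
                    original_time = parse_time(ifelse(df$original_time == "",
                                                      NA, df$original_time)),
                    stringsAsFactors = FALSE)
  class(out) <- c("twilight_set", "data.frame")
  out
}

#' Write / read a track (CSV); GeoJSON export of the median line
#'
#' @param track Track data.frame (`date`, `lat`, `lon`, `lat_sd`,
#'   `lon_sd`, optionally `rise`/`set`).
#' @param path File path.
#' @export
write_track_csv <- function(track, path) {
  df <- track
  df$date <- format(df$date)
  for (cl in intersect(c("rise", "set", "sunrise", "sunset"), names(df)))
    df[[cl]] <- fmt_time(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "lat", "lon") %in% names(df)))
    stop("track CSV must have columns date, lat, lon")
  df$date <- as.Date(df$date)
  for (cl in intersect(c("rise", "set", "sunrise", "sunset"), names(df)))
    df[[cl]] <- parse_time(df[[cl]])
  df
}

#' @rdname write_track_csv
#' @export
write_track_geojson <- function(track, path) {
  gj <- list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(track)), function(i)
                      c(track$lon[i], track$lat[i]))),
    properties = list(dates = format(track$date)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Write / read gridded weather fields (text format)
#'
#' A self-describing plain-text format: first line a `#`-prefixed JSON
#' header with the axes, then a long CSV (`var`, `level`, `itime`, `ilat`,
#' `ilon`, `value`). Dimension order on disk is irrelevant: indices are
#' named. Round-trips are lossless at full double precision.
#'
#' @param fields An [env_fields()].
#' @param path File path.
#' @export
write_env_fields <- function(fields, path) {
  hdr <- list(times = fmt_time(fields$times), lats = fields$lats,
              lons = fields$lons, levels = fields$levels,
              land = if (!is.null(fields$land)) which(fields$land) else NULL,
              vars3 = c("temp", "sp", "u_sfc", "v_sfc", "prate"),
              vars4 = c("u_lev", "v_lev"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)), con)
  writeLines("var,level,itime,ilat,ilon,value", con)
  for (v in hdr$vars3) {
    arr <- fields[[v]]
    idx <- which(arr != 0, arr.ind = TRUE)
    if (nrow(idx))
      writeLines(sprintf("%s,0,%d,%d,%d,%.17g", v, idx[, 1], idx[, 2], idx[, 3],
                         arr[idx]), con)
  }
  for (v in hdr$vars4) {
    arr <- fields[[v]]
    idx <- which(arr != 0, arr.ind = TRUE)
    if (nrow(idx))
      writeLines(sprintf("%s,%d,%d,%d,%d,%.17g", v, idx[, 4], idx[, 1],
                         idx[, 2], idx[, 3], arr[idx]), con)
  }
  invisible(path)
}

#' @rdname write_env_fields
#' @export
read_env_fields <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) stop("missing JSON header line")
  hdr <- jsonlite::fromJSON(substring(first, 2))
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  nt <- length(hdr$times); nla <- length(hdr$lats); nlo <- length(hdr$lons)
  nlev <- length(hdr$levels)
  mk3 <- function(v) {
    arr <- array(0, c(nt, nla, nlo))
    sel <- df$var == v
    arr[cbind(df$itime[sel], df$ilat[sel], df$ilon[sel])] <- df$value[sel]
    arr
  }
  mk4 <- function(v) {
    arr <- array(0, c(nt, nla, nlo, nlev))
    sel <- df$var == v
    arr[cbind(df$itime[sel], df$ilat[sel], df$ilon[sel], df$level[sel])] <- df$value[sel]
    arr
  }
  land <- NULL
  if (!is.null(hdr$land)) {
    land <- matrix(FALSE, nla, nlo)
    land[hdr$land] <- TRUE
  }
  env_fields(parse_time(hdr$times), hdr$lats, hdr$lons,
             temp = mk3("temp"), sp = mk3("sp"), u_sfc = mk3("u_sfc"),
             v_sfc = mk3("v_sfc"), prate = mk3("prate"),
             u_lev = mk4("u_lev"), v_lev = mk4("v_lev"),
             levels = hdr$levels, land = land)
}

#' Write / read a bird-day table (CSV)
#'
#' @param x A `bird_day_table`.
#' @param path File path.
#' @export
write_bird_days_csv <- function(x, path) {
  df <- as.data.frame(x)
  df$date <- format(df$date)
  df$sunset <- fmt_time(df$sunset)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bird_days_csv
#' @export
read_bird_days_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird", "year", "date", "day_type", "lat", "lon", "sunset",
            "temperature", "precipitation", "pressure", "wind_speed",
            "flow_assistance", "remaining_distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bird-day CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df$sunset <- parse_time(df$sunset)
  class(df) <- c("bird_day_table", "data.frame")
  df
}

#' Write / read a pipeline configuration (YAML)
#'
#' Round-trips a [pipeline_config()] through YAML unchanged.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "mcmc")])
  if (!is.null(raw$mcmc)) cfg$mcmc <- raw$mcmc
  cfg
}

#' Write a fit result as JSON
#'
#' @param fit A `fit_result`.
#' @param cri A `cri_table` from [posterior_sim()].
#' @param path File path.
#' @export
write_fit_json <- function(fit, cri, path) {
  r2 <- r_squared(fit)
  out <- list(
    family = fit$family,
    n = fit$n, n_dropped = fit$n_dropped,
    terms = lapply(seq_len(nrow(cri)), function(i)
      list(term = cri$term[i], estimate = cri$estimate[i],
           lower = cri$lower[i], upper = cri$upper[i],
           significant = cri$significant[i])),
    random_sd = if (is.na(fit$random_sd)) NULL else fit$random_sd,
    resid_sd = if (is.na(fit$resid_sd)) NULL else fit$resid_sd,
    scale_parameter = if (is.na(fit$scale_parameter)) NULL else fit$scale_parameter,
    marginal_r2 = unname(r2["marginal"]),
    conditional_r2 = unname(r2["conditional"]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(path)
}
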