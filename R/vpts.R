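# Vertical-profile time series: domain types, VPTS-CSV I/O, vertical
# integration into migration-traffic quantities.

BIN_WIDTH_M <- 100
MAX_HEIGHT_M <- 5000
DELTA_H_KM <- BIN_WIDTH_M / 1000

#' Station configuration
#'
#' Describes one weather radar: identifier, coordinates, antenna height and
#' civil UTC offset used for night labelling.
#'
#' @param id Station identifier (e.g. `"BAR"`).
#' @param lat,lon Latitude and longitude in decimal degrees.
#' @param height_m Antenna height, metres above sea level.
#' @param utc_offset Civil UTC offset in hours. Defaults to the longitude's
#'   solar offset rounded to the nearest hour.
#' @return A `station_config` list.
#' @export
station_config <- function(id, lat, lon, height_m = 0,
                           utc_offset = round(lon / 15)) {
  stopifnot(is.character(id), length(id) == 1,
            is.finite(lat), abs(lat) <= 90,
            is.finite(lon), abs(lon) <= 180,
            is.finite(height_m))
  structure(list(id = id, lat = lat, lon = lon, height_m = height_m,
                 utc_offset = utc_offset),
            class = "station_config")
}

#' Construct a vertical-profile time series
#'
#' Bundles a long-format table of 100 m altitude bins (one row per
#' timestamp x height) with its station metadata and validates the core
#' invariants: heights on the 0-4900 m grid, non-negative linear
#' reflectivity, unique (timestamp, height) keys.
#'
#' @param data Data frame with columns `datetime` (POSIXct UTC or ISO-8601
#'   string), `height` (bin lower bound, m a.s.l.), `eta` (linear reflectivity,
#'   cm2 km-3), `u`, `v` (reflectivity-weighted mean ground velocity, m s-1;
#'   `NA` = missing).
#' @param station A [station_config()].
#' @return An object of class `vpts`: list with elements `station` and `data`
#'   (sorted by time then height, with a logical `velocity_ok` column).
#' @export
as_vpts <- function(data, station) {
  stopifnot(inherits(station, "station_config"))
  need <- c("datetime", "height", "eta", "u", "v")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!inherits(data$datetime, "POSIXct")) {
    data$datetime <- parse_utc(data$datetime)
  }
  attr(data$datetime, "tzone") <- "UTC"
  bad_h <- which(!(data$height %in% seq(0, MAX_HEIGHT_M - BIN_WIDTH_M,
                                        by = BIN_WIDTH_M)))
  if (length(bad_h)) {
    stop(sprintf("height not on the %d m bin grid below %d m at row(s) %s",
                 BIN_WIDTH_M, MAX_HEIGHT_M,
                 paste(utils::head(bad_h, 3), collapse = ", ")), call. = FALSE)
  }
  if (any(data$eta < 0, na.rm = TRUE)) {
    stop("negative reflectivity (eta) is not allowed", call. = FALSE)
  }
  key <- paste(fmt_utc(data$datetime), data$height)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (timestamp, height) pair: ", d, call. = FALSE)
  }
  ord <- order(data$datetime, data$height)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  data$velocity_ok <- is.finite(data$u) & is.finite(data$v)
  data$u[!data$velocity_ok] <- NA_real_
  data$v[!data$velocity_ok] <- NA_real_
  structure(list(station = station, data = data), class = "vpts")
}

#' @export
print.vpts <- function(x, ...) {
  ts <- unique(x$data$datetime)
  cat(sprintf("Vertical-profile time series: station %s, %d profiles, %d bins\n",
              x$station$id, length(ts), nrow(x$data)))
  if (length(ts)) {
    cat(sprintf("  %s .. %s UTC\n", fmt_utc(min(ts)), fmt_utc(max(ts))))
  }
  invisible(x)
}

#' Read a VPTS-CSV file
#'
#' Dialect: UTF-8, comma-separated, columns `radar,datetime,height,eta,u,v`
#' (an optional `source` column is carried through but ignored by all core
#' operations). `datetime` is ISO-8601 UTC; `height` is the bin lower bound in
#' metres above sea level; empty velocity fields are missing, not zero.
#'
#' @param path Path to the file.
#' @param station A [station_config()]; its `id` must match the file's
#'   `radar` column when that column is non-empty.
#' @return A [as_vpts()] object sorted by time.
#' @export
read_vpts <- function(path, station) {
  if (!file.exists(path)) stop("cannot read VPTS file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("radar", "datetime", "height", "eta", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("VPTS file lacks mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) && any(nzchar(df$radar)) &&
      !all(df$radar[nzchar(df$radar)] == station$id)) {
    stop("radar column does not match station id '", station$id, "'",
         call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$height))) |
                 !is.finite(suppressWarnings(as.numeric(df$eta))))
  if (length(bad)) {
    stop(sprintf("malformed height/eta at data line(s) %s of %s",
                 paste(utils::head(bad + 1, 5), collapse = ", "), path),
         call. = FALSE)
  }
  df$height <- as.numeric(df$height)
  df$eta <- as.numeric(df$eta)
  df$u <- suppressWarnings(as.numeric(df$u))
  df$v <- suppressWarnings(as.numeric(df$v))
  keep <- intersect(c("datetime", "height", "eta", "u", "v", "source"),
                    names(df))
  as_vpts(df[keep], station)
}

#' Write a VPTS-CSV file
#'
#' Inverse of [read_vpts()]: `read_vpts(write_vpts(x))` reproduces `x` on all
#' declared fields, including velocity missingness. Partitioned series
#' (see [partition_series()]) additionally serialize
#' `eta_bird,f_bird,heading,track`.
#'
#' @param x A `vpts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vpts <- function(x, path) {
  stopifnot(inherits(x, "vpts"))
  d <- x$data
  out <- data.frame(radar = rep(x$station$id, nrow(d)),
                    datetime = fmt_utc(d$datetime),
                    height = d$height, eta = d$eta, u = d$u, v = d$v,
                    stringsAsFactors = FALSE)
  for (col in c("source", "eta_bird", "f_bird", "heading", "track")) {
    if (col %in% names(d)) out[[col]] <- d[[col]]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Reflectivity to animal density
#'
#' Converts linear reflectivity eta (cm2 km-3) into animal density
#' (birds km-3) by dividing by an assumed single-bird radar cross section,
#' 11 cm2 by default.
#'
#' @param eta Linear reflectivity, cm2 km-3 (non-negative).
#' @param rcs Radar cross section per bird, cm2.
#' @return Density in birds km-3.
#' @export
bin_density <- function(eta, rcs = 11) {
  stopifnot(is.numeric(rcs), length(rcs) == 1, rcs > 0)
  if (any(eta < 0, na.rm = TRUE)) {
    stop("negative reflectivity", call. = FALSE)
  }
  eta / rcs
}

# Ground speed in km/h from velocity components in m/s.
speed_kmh <- function(u, v) sqrt(u^2 + v^2) * 3.6

#' Vertically integrate a profile time series
#'
#' For every profile, integrates densities over 100 m altitude bins
#' (rectangle rule) into vertically integrated density
#' VID = sum(dens * dh) (birds km-2), migration traffic rate
#' MTR = sum(dens * speed * dh) (birds km-1 h-1) with speed the ground speed in
#' km h-1, and the density-weighted mean flight height over bin centres. MTR
#' is reported missing whenever any bin with positive density lacks a velocity
#' estimate: partial-bin traffic rates are never silently computed.
#'
#' @param x A `vpts` object (optionally partitioned).
#' @param rcs Radar cross section per bird, cm2.
#' @param use `"total"` integrates total reflectivity with observed mixture
#'   velocities; `"bird"` (requires a partitioned series) integrates
#'   bird-reflectivity with the bird ground-velocity components.
#' @return Data frame with one row per profile: `datetime`, `vid`, `mtr`,
#'   `mean_height` (m a.s.l.), `n_bins_used`.
#' @export
integrate_profile <- function(x, rcs = 11, use = c("total", "bird")) {
  stopifnot(inherits(x, "vpts"))
  use <- match.arg(use)
  d <- x$data
  if (use == "bird") {
    if (!all(c("eta_bird", "u_bird", "v_bird") %in% names(d))) {
      stop("series is not partitioned; run partition_series() first",
           call. = FALSE)
    }
    eta <- d$eta_bird
    u <- d$u_bird
    v <- d$v_bird
    vel_ok <- is.finite(u) & is.finite(v)
  } else {
    eta <- d$eta
    u <- d$u
    v <- d$v
    vel_ok <- d$velocity_ok
  }
  dens <- bin_density(ifelse(is.finite(eta), eta, 0), rcs)
  centre <- d$height + BIN_WIDTH_M / 2
  spd <- speed_kmh(u, v)
  f <- factor(fmt_utc(d$datetime), levels = unique(fmt_utc(d$datetime)))
  vid <- as.numeric(tapply(dens * DELTA_H_KM, f, sum))
  mtr_part <- ifelse(vel_ok, dens * spd * DELTA_H_KM, 0)
  mtr <- as.numeric(tapply(mtr_part, f, sum))
  broken <- as.logical(tapply(dens > 0 & !vel_ok, f, any))
  mtr[broken] <- NA_real_
  wsum <- as.numeric(tapply(dens, f, sum))
  hsum <- as.numeric(tapply(dens * centre, f, sum))
  mean_height <- ifelse(wsum > 0, hsum / wsum, NA_real_)
  data.frame(datetime = unique(d$datetime),
             vid = vid, mtr = mtr, mean_height = mean_height,
             n_bins_used = as.integer(tapply(dens >= 0, f, sum)),
             row.names = NULL)
}

#' Normalized altitude profile of density
#'
#' Divides per-bin density by the vertically integrated density (dens/VID),
#' yielding unitless-per-km weights whose altitude integral is 1. Isolates
#' altitude selection from nightly abundance.
#'
#' @param x A `vpts` object.
#' @param rcs Radar cross section per bird, cm2.
#' @return The input table with an added `dens_norm` column (km-1);
#'   `sum(dens_norm) * 0.1 == 1` within each profile.
#' @export
normalized_density <- function(x, rcs = 11) {
  stopifnot(inherits(x, "vpts"))
  d <- x$data
  dens <- bin_density(ifelse(is.finite(d$eta), d$eta, 0), rcs)
  key <- fmt_utc(d$datetime)
  vid <- tapply(dens * DELTA_H_KM, key, sum)[key]
  if (any(vid == 0)) {
    stop("profile with zero vertically integrated density at ",
         names(which(vid == 0))[1], call. = FALSE)
  }
  d$dens_norm <- dens / as.numeric(vid)
  d
}
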