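# Pairing of profile time series with gridded pressure-level atmospheric data,
# flow assistance along the preferred migratory direction, covariate assembly
# helpers, and wind-source validation.

ATM_VARS <- c("u_wind", "v_wind", "temp", "shum", "omega", "tke")

#' Construct an atmospheric grid
#'
#' Three-hourly pressure-level table for the grid point nearest a radar:
#' one row per (time, level) with geopotential height, wind components,
#' temperature, specific humidity, vertical motion (omega) and turbulent
#' kinetic energy.
#'
#' @param data Data frame with columns `time` (POSIXct UTC or ISO string),
#'   `level_hPa`, `gph_m`, `u`, `v`, `temp_K`, `shum`, `omega`, `tke`.
#' @return An `atmos_grid` object; rows sorted by time then decreasing
#'   pressure, with geopotential height strictly increasing within each time.
#' @export
as_atmos_grid <- function(data) {
  need <- c("time", "level_hPa", "gph_m", "u", "v", "temp_K", "shum",
            "omega", "tke")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("atmosphere table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)
  if (!inherits(data$time, "POSIXct")) data$time <- parse_utc(data$time, "time")
  attr(data$time, "tzone") <- "UTC"
  data <- data[order(data$time, -data$level_hPa), , drop = FALSE]
  rownames(data) <- NULL
  mono <- tapply(data$gph_m, fmt_utc(data$time),
                 function(z) all(diff(z) > 0))
  if (!all(mono)) {
    stop("geopotential height must increase as pressure decreases",
         call. = FALSE)
  }
  structure(list(data = data,
                 times = sort(unique(data$time)),
                 levels = sort(unique(data$level_hPa), decreasing = TRUE)),
            class = "atmos_grid")
}

#' Read an atmospheric grid-point table from CSV
#'
#' @param path CSV with the columns documented in [as_atmos_grid()].
#' @return An `atmos_grid` object.
#' @export
read_atmosphere <- function(path) {
  if (!file.exists(path)) stop("cannot read atmosphere file: ", path,
                               call. = FALSE)
  as_atmos_grid(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an atmospheric grid-point table to CSV
#'
#' @param grid An `atmos_grid` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atmosphere <- function(grid, path) {
  stopifnot(inherits(grid, "atmos_grid"))
  out <- grid$data
  out$time <- fmt_utc(out$time)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pair a profile time series with atmospheric data
#'
#' For each profile timestamp every grid variable is linearly interpolated in
#' time between the bracketing 3-hourly instants at each pressure level, then
#' linearly interpolated in altitude from the (time-interpolated) level
#' geopotential heights to the altitude-bin centres. Below the lowest and
#' above the highest level height, values clamp to the nearest level rather
#' than extrapolate. Timestamps outside the grid's time span yield missing
#' values with a warning.
#'
#' @param x A `vpts` object.
#' @param grid An `atmos_grid` object.
#' @return Data frame keyed by (`datetime`, `height`) with interpolated
#'   columns `u_wind`, `v_wind`, `temp`, `shum`, `omega`, `tke` and an
#'   `in_span` flag.
#' @export
pair_weather <- function(x, grid) {
  stopifnot(inherits(x, "vpts"), inherits(grid, "atmos_grid"))
  ts <- unique(x$data$datetime)
  gt <- as.numeric(grid$times)
  tnum <- as.numeric(ts)
  in_span <- tnum >= min(gt) & tnum <= max(gt)
  if (any(!in_span)) {
    warning(sum(!in_span), " profile timestamp(s) outside atmospheric grid ",
            "span; values set missing", call. = FALSE)
  }
  gd <- grid$data
  nl <- length(grid$levels)
  # matrices [level x grid-time] per variable, plus gph
  ord <- order(match(gd$level_hPa, grid$levels), gd$time)
  gd <- gd[ord, , drop = FALSE]
  mk <- function(col) matrix(gd[[col]], nrow = length(gt), ncol = nl)
  gph_m <- mk("gph_m")
  varm <- list(u_wind = mk("u"), v_wind = mk("v"), temp = mk("temp_K"),
               shum = mk("shum"), omega = mk("omega"), tke = mk("tke"))
  # time interpolation: [profile-time x level]
  tinterp <- function(m) {
    cols <- lapply(seq_len(ncol(m)), function(j) {
      out <- rep(NA_real_, length(tnum))
      if (length(gt) == 1) {
        out[tnum == gt] <- m[1, j]
      } else if (any(in_span)) {
        out[in_span] <- stats::approx(gt, m[, j], xout = tnum[in_span])$y
      }
      out
    })
    matrix(unlist(cols), nrow = length(tnum), ncol = ncol(m))
  }
  gph_t <- tinterp(gph_m)
  var_t <- lapply(varm, tinterp)
  d <- x$data[c("datetime", "height")]
  d$centre <- d$height + BIN_WIDTH_M / 2
  idx <- match(d$datetime, ts)
  for (vn in names(var_t)) d[[vn]] <- NA_real_
  for (i in seq_along(ts)) {
    rows <- which(idx == i)
    if (!in_span[i] || !length(rows)) next
    z <- gph_t[i, ]
    for (vn in names(var_t)) {
      d[[vn]][rows] <- stats::approx(z, var_t[[vn]][i, ],
                                     xout = d$centre[rows], rule = 2)$y
    }
  }
  d$in_span <- in_span[idx]
  d$centre <- NULL
  d
}

#' Flow assistance along the preferred migratory direction
#'
#' EQ-airspeed flow assistance: a bird flying at fixed airspeed `a` fully
#' compensates crosswind and the assistance is the ground-speed gain along the
#' preferred direction, `t + sqrt(a^2 - c^2) - a`, where `t` and `c` are the
#' wind components along and across the preferred direction. When the
#' crosswind exceeds the airspeed, full compensation is infeasible and the
#' result is missing.
#'
#' @param u_wind,v_wind Wind components, m s-1.
#' @param preferred_direction Compass degrees of the preferred migratory
#'   direction (0 = north).
#' @param airspeed Assumed bird airspeed, m s-1 (default 8).
#' @return Flow assistance in m s-1; `NA` where `|crosswind| > airspeed`.
#' @export
tailwind_eq_airspeed <- function(u_wind, v_wind, preferred_direction,
                                 airspeed = 8) {
  stopifnot(airspeed > 0)
  th <- (preferred_direction %% 360) * DEG2RAD
  tw <- u_wind * sin(th) + v_wind * cos(th)
  cw <- u_wind * cos(th) - v_wind * sin(th)
  out <- tw + sqrt(pmax(airspeed^2 - cw^2, 0)) - airspeed
  out[abs(cw) > airspeed] <- NA_real_
  out
}

#' Seasonally preferred migratory direction
#'
#' Bird-reflectivity-weighted circular mean of track directions for one
#' station-season subset; this is the "preferred migratory direction" fed to
#' [tailwind_eq_airspeed()].
#'
#' @param track Track (ground-direction) in compass degrees.
#' @param eta_bird Bird reflectivity weights, cm2 km-3.
#' @return Compass degrees in `[0, 360)`.
#' @export
preferred_direction <- function(track, eta_bird) {
  ok <- is.finite(track) & is.finite(eta_bird) & eta_bird > 0
  if (!any(ok)) stop("no bins with positive bird reflectivity", call. = FALSE)
  th <- track[ok] * DEG2RAD
  w <- eta_bird[ok]
  bearing_from_uv(sum(w * sin(th)), sum(w * cos(th)))
}

#' Value of a paired variable at ground level
#'
#' Returns, per timestamp, the variable from the altitude bin whose centre is
#' closest to the station's ground height; ties resolve to the lower bin.
#'
#' @param paired Output of [pair_weather()].
#' @param variable One of `"u_wind"`, `"v_wind"`, `"temp"`, `"shum"`,
#'   `"omega"`, `"tke"`.
#' @param station A [station_config()] (its `height_m` defines ground).
#' @return Data frame `datetime`, `height`, value column named `variable`.
#' @export
ground_level_value <- function(paired, variable, station) {
  variable <- match.arg(variable, ATM_VARS)
  if (!nrow(paired)) stop("no bins", call. = FALSE)
  centre <- paired$height + BIN_WIDTH_M / 2
  dist <- abs(centre - station$height_m)
  split_rows <- split(seq_len(nrow(paired)), fmt_utc(paired$datetime))
  pick <- vapply(split_rows, function(rows) {
    d <- dist[rows]
    cand <- rows[d == min(d)]
    cand[which.min(paired$height[cand])]
  }, integer(1))
  out <- paired[sort(unname(pick)), c("datetime", "height", variable)]
  rownames(out) <- NULL
  out
}

#' Greedy collinearity screen on a covariate table
#'
#' Walks covariate pairs whose absolute Pearson correlation exceeds the
#' threshold and drops the lower-priority member of each, so the retained set
#' is deterministic given the priority order. Constant columns (undefined
#' correlation) are excluded from screening with a warning.
#'
#' @param covariates Data frame of numeric covariates.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @param priority Character vector naming all columns, highest priority
#'   first; defaults to column order.
#' @return Character vector of retained covariate names.
#' @export
collinearity_screen <- function(covariates, threshold = 0.7,
                                priority = names(covariates)) {
  stopifnot(ncol(covariates) >= 2, nrow(covariates) >= 3,
            setequal(priority, names(covariates)))
  keep <- priority
  const <- vapply(covariates, function(z) stats::sd(z, na.rm = TRUE) == 0 ||
                    all(is.na(z)), logical(1))
  if (any(const)) {
    warning("constant column(s) excluded from screening: ",
            paste(names(covariates)[const], collapse = ", "), call. = FALSE)
    keep <- setdiff(keep, names(covariates)[const])
  }
  i <- 1
  while (i < length(keep)) {
    hi <- keep[i]
    drop <- character(0)
    for (lo in keep[-seq_len(i)]) {
      r <- stats::cor(covariates[[hi]], covariates[[lo]],
                      use = "complete.obs")
      if (is.finite(r) && abs(r) > threshold) drop <- c(drop, lo)
    }
    keep <- setdiff(keep, drop)
    i <- i + 1
  }
  keep
}

#' Mean absolute wind-speed difference between two matched sources
#'
#' Validation statistic for a modelled wind product against balloon soundings:
#' the mean of `|speed_a - speed_b|` over records matched on time and height.
#'
#' @param speed_a,speed_b Matched wind speeds, m s-1.
#' @return Mean absolute difference, m s-1.
#' @export
wind_mad <- function(speed_a, speed_b) {
  ok <- is.finite(speed_a) & is.finite(speed_b)
  if (!any(ok)) stop("zero matched wind records", call. = FALSE)
  mean(abs(speed_a[ok] - speed_b[ok]))
}
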