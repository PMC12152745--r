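# Bird-insect echo partitioning by airspeed.
#
# The observed reflectivity-weighted mean velocity of a radar bin is modelled
# as a mixture of two target classes: birds are self-propelled at a fixed
# airspeed a_b along an unknown heading, and insects drift with the wind plus
# a small fixed self-propulsion a_i oriented downwind. Writing
# A = V_obs - V_wind (the mixture's air velocity) and w-hat the downwind unit
# vector, the bird fraction f satisfies
#
#   |A - (1 - f) a_i w-hat| = f a_b,
#
# a scalar quadratic in f:
#   f^2 (a_i^2 - a_b^2) + 2 f a_i (A.w - a_i) + |A - a_i w-hat|^2 = 0.
#
# Its value at f = 0 is |A - a_i w-hat|^2 >= 0 and at f = 1 is |A|^2 - a_b^2,
# so whenever the mixture airspeed |A| < a_b there is a sign change and a
# unique root in [0, 1]; |A| >= a_b forces f = 1 with a recorded residual.

#' Partitioning parameters
#'
#' Fixed airspeeds for the two target classes: 8 m s-1 for birds and
#' 1 m s-1 for insects by default, representative of sustained passerine and
#' insect self-propelled flight. Under calm wind (speed below
#' `calm_wind_eps`) the downwind direction is undefined and the insect
#' self-propulsion term is dropped.
#'
#' @param a_bird Bird airspeed, m s-1.
#' @param a_insect Insect airspeed, m s-1 (must be below `a_bird`).
#' @param calm_wind_eps Wind-speed threshold below which wind is calm, m s-1.
#' @return A `partition_params` list.
#' @export
partition_params <- function(a_bird = 8, a_insect = 1, calm_wind_eps = 0.5) {
  stopifnot(a_insect >= 0, a_insect < a_bird)
  structure(list(a_bird = a_bird, a_insect = a_insect,
                 calm_wind_eps = calm_wind_eps),
            class = "partition_params")
}

#' Partition one altitude bin into bird and insect components
#'
#' Solves the airspeed-mixture model for the bird fraction `f` of a bin's
#' reflectivity, the bird self-propulsion (air-velocity) vector of magnitude
#' `a_bird`, and the derived heading and track. Vectorized over bins.
#'
#' @param u_obs,v_obs Observed reflectivity-weighted mean ground velocity,
#'   m s-1.
#' @param u_wind,v_wind Wind components at the bin, m s-1.
#' @param eta_total Linear reflectivity of the bin, cm2 km-3.
#' @param params A [partition_params()].
#' @return Data frame with columns `f_bird`, `u_air_bird`, `v_air_bird`,
#'   `heading`, `track`, `airspeed_obs`, `eta_bird`, `residual` (m s-1 model
#'   misfit, zero unless the root was clamped to 0 or 1).
#' @export
partition_bin <- function(u_obs, v_obs, u_wind, v_wind, eta_total,
                          params = partition_params()) {
  if (any(eta_total < 0, na.rm = TRUE)) {
    stop("negative reflectivity", call. = FALSE)
  }
  n <- max(length(u_obs), length(v_obs), length(u_wind), length(v_wind),
           length(eta_total))
  u_obs <- rep_len(u_obs, n); v_obs <- rep_len(v_obs, n)
  u_wind <- rep_len(u_wind, n); v_wind <- rep_len(v_wind, n)
  eta_total <- rep_len(eta_total, n)
  a_b <- params$a_bird
  a_i <- params$a_insect

  Au <- u_obs - u_wind
  Av <- v_obs - v_wind
  Amag <- sqrt(Au^2 + Av^2)
  wspd <- sqrt(u_wind^2 + v_wind^2)
  calm <- !is.na(wspd) & wspd < params$calm_wind_eps
  wu <- ifelse(calm, 0, u_wind / wspd)
  wv <- ifelse(calm, 0, v_wind / wspd)
  ai_eff <- ifelse(calm, 0, a_i)

  Aw <- Au * wu + Av * wv
  c0 <- (Au - ai_eff * wu)^2 + (Av - ai_eff * wv)^2  # value at f = 0
  qa <- ai_eff^2 - a_b^2
  qb <- 2 * ai_eff * (Aw - ai_eff)

  f <- rep(NA_real_, n)
  ok <- is.finite(Au) & is.finite(Av) & is.finite(u_wind) & is.finite(v_wind)
  # |A| >= a_b: observed mixture airspeed already at or beyond bird airspeed
  hi <- ok & Amag >= a_b
  f[hi] <- 1
  lo <- ok & !hi
  # unique root in [0, 1]: qa < 0 always, value at 0 is c0 >= 0, at 1 < 0
  disc <- qb[lo]^2 - 4 * qa[lo] * c0[lo]
  disc[disc < 0] <- 0  # numerically tangent case
  r1 <- (-qb[lo] + sqrt(disc)) / (2 * qa[lo])
  r2 <- (-qb[lo] - sqrt(disc)) / (2 * qa[lo])
  # qa < 0: the parabola opens downward, is >= 0 at f = 0 and < 0 at f = 1,
  # so the larger root is the unique root in [0, 1]
  f[lo] <- pmin(pmax(pmax(r1, r2), 0), 1)

  # bird air-velocity: direction of A - (1-f) a_i w-hat, magnitude a_b
  ru <- Au - (1 - f) * ai_eff * wu
  rv <- Av - (1 - f) * ai_eff * wv
  rmag <- sqrt(ru^2 + rv^2)
  pos <- ok & f > 0 & rmag > 0
  u_air <- ifelse(pos, a_b * ru / rmag, NA_real_)
  v_air <- ifelse(pos, a_b * rv / rmag, NA_real_)
  residual <- ifelse(ok, abs(rmag - f * a_b), NA_real_)

  heading <- bearing_from_uv(u_air, v_air)
  track <- bearing_from_uv(u_air + u_wind, v_air + v_wind)
  data.frame(f_bird = f,
             u_air_bird = u_air, v_air_bird = v_air,
             heading = heading, track = track,
             airspeed_obs = ifelse(ok, Amag, NA_real_),
             eta_bird = f * eta_total,
             residual = residual)
}

#' Heading from air-velocity components
#'
#' Compass direction (0 = north, 90 = east) of the bird self-propulsion
#' vector.
#'
#' @param u_air,v_air Air-velocity components, m s-1 (not both zero).
#' @return Compass degrees in `[0, 360)`.
#' @export
heading_from_uv <- function(u_air, v_air) {
  if (any(u_air == 0 & v_air == 0, na.rm = TRUE)) {
    stop("heading undefined for zero air velocity", call. = FALSE)
  }
  bearing_from_uv(u_air, v_air)
}

#' Track from air velocity and wind
#'
#' Compass direction of the bird ground velocity, the vector sum of the air
#' velocity and the wind.
#'
#' @param u_air,v_air Air-velocity components, m s-1.
#' @param u_wind,v_wind Wind components, m s-1.
#' @return Compass degrees in `[0, 360)`.
#' @export
track_from_air <- function(u_air, v_air, u_wind, v_wind) {
  gu <- u_air + u_wind
  gv <- v_air + v_wind
  if (any(gu == 0 & gv == 0, na.rm = TRUE)) {
    stop("track undefined for zero ground velocity", call. = FALSE)
  }
  bearing_from_uv(gu, gv)
}

#' Partition a whole profile time series
#'
#' Applies [partition_bin()] to every altitude bin using the paired wind, and
#' adds `f_bird`, `eta_bird`, `heading`, `track` plus the bird ground-velocity
#' components `u_bird`, `v_bird` to the series. Bins with missing velocity or
#' missing wind yield missing partitions.
#'
#' @param x A `vpts` object.
#' @param paired Output of [pair_weather()] aligned with `x` (same
#'   (`datetime`, `height`) keys).
#' @param params A [partition_params()].
#' @return The input `vpts` with partition columns added.
#' @export
partition_series <- function(x, paired, params = partition_params()) {
  stopifnot(inherits(x, "vpts"))
  d <- x$data
  key_x <- paste(fmt_utc(d$datetime), d$height)
  key_p <- paste(fmt_utc(paired$datetime), paired$height)
  idx <- match(key_x, key_p)
  if (anyNA(idx)) {
    stop("paired weather is missing ", sum(is.na(idx)),
         " (timestamp, height) bin(s) of the series", call. = FALSE)
  }
  uw <- paired$u_wind[idx]
  vw <- paired$v_wind[idx]
  res <- partition_bin(d$u, d$v, uw, vw, d$eta, params)
  d$f_bird <- res$f_bird
  d$eta_bird <- res$eta_bird
  d$heading <- res$heading
  d$track <- res$track
  d$u_bird <- res$u_air_bird + uw
  d$v_bird <- res$v_air_bird + vw
  d$residual <- res$residual
  x$data <- d
  x
}

#' Scalar airspeed-interpolation bird fraction (diagnostic)
#'
#' The simple one-dimensional fallback: linear interpolation of the observed
#' mixture airspeed between the insect and bird airspeeds,
#' `clip((|V_obs - V_wind| - a_i) / (a_b - a_i), 0, 1)`. Provided as a
#' diagnostic; the vector mixture model of [partition_bin()] is the default.
#'
#' @inheritParams partition_bin
#' @return Bird fraction in `[0, 1]`.
#' @export
partition_scalar <- function(u_obs, v_obs, u_wind, v_wind,
                             params = partition_params()) {
  amag <- sqrt((u_obs - u_wind)^2 + (v_obs - v_wind)^2)
  pmin(pmax((amag - params$a_insect) / (params$a_bird - params$a_insect),
            0), 1)
}

#' Brute-force grid-search partition reference
#'
#' Independent check of the closed-form quadratic in [partition_bin()]:
#' exhaustively scans bird fraction f on a uniform grid and heading on a
#' uniform angular grid, returning the (f, heading) minimizing the mixture
#' residual `|A - f a_b h-hat - (1-f) a_i w-hat|`. Orders of magnitude slower
#' than the closed form; intended for validation only.
#'
#' @inheritParams partition_bin
#' @param f_step Grid step in f (default 1e-3).
#' @param theta_step_deg Heading grid step in degrees (default 0.1).
#' @return Data frame `f_bird`, `heading`, `residual`.
#' @export
partition_grid_oracle <- function(u_obs, v_obs, u_wind, v_wind,
                                  params = partition_params(),
                                  f_step = 1e-3, theta_step_deg = 0.1) {
  n <- max(length(u_obs), length(v_obs), length(u_wind), length(v_wind))
  u_obs <- rep_len(u_obs, n); v_obs <- rep_len(v_obs, n)
  u_wind <- rep_len(u_wind, n); v_wind <- rep_len(v_wind, n)
  wspd <- sqrt(u_wind^2 + v_wind^2)
  calm <- wspd < params$calm_wind_eps
  wu <- ifelse(calm, 0, u_wind / wspd)
  wv <- ifelse(calm, 0, v_wind / wspd)
  ai <- ifelse(calm, 0, params$a_insect)
  m <- grid_oracle_cpp(u_obs - u_wind, v_obs - v_wind, wu, wv, ai,
                       params$a_bird, f_step, theta_step_deg)
  data.frame(f_bird = m[, 1], heading = m[, 2], residual = m[, 3])
}
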