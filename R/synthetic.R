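# Synthetic-data generator: profile time series, atmospheric grids and
# acoustic logs with a known ground truth (seasonal passage curve with
# tunable night-to-night variability, a nocturnal low-level jet, bird echoes
# self-propelled at fixed airspeed, insect echoes drifting with the wind,
# height-dependent call detectability), so every pipeline stage has a
# recoverable truth.

#' Ground-truth scenario parameters
#'
#' All knobs of the synthetic scenario. Defaults describe a tropical fall
#' season: a Gaussian passage curve peaking in early October, a modest
#' night-effect lognormal sd (steady migration), a stable south-eastward
#' nocturnal low-level jet centred at 1750 m, birds at 8 m s-1 airspeed
#' heading south, insects at 1 m s-1 drifting downwind.
#'
#' @param season_start,season_end Season window (local dates).
#' @param total_passage Season total migration traffic, birds km-1.
#' @param peak_day Date of the passage-curve peak.
#' @param passage_sd Passage-curve sd, days.
#' @param night_sigma Lognormal sd of nightly multipliers (episodicity knob).
#' @param jet List: `center_height` (m), `width` (m), `direction` (compass
#'   deg the jet blows toward), `speed` (m s-1), `ar_phi`, `ar_sd` (nightly
#'   AR(1) perturbation), `day_factor` (daytime attenuation).
#' @param base_wind List: `speed` (m s-1), `direction` (deg),
#'   `period_days` of its slow sinusoidal variation, `amp` (fractional).
#' @param bird List: `airspeed` (m s-1), `heading` (preferred, deg),
#'   `kappa` (von Mises heading concentration; `Inf` = no scatter).
#' @param insect List: `airspeed` (m s-1), `eta_base` (cm2 km-3),
#'   `scale_height` (m), `diel_amp` (within-night modulation).
#' @param altitude List: `scale_height` (m, bird density e-folding),
#'   `kappa_w` (tailwind altitude-preference weight, per m s-1).
#' @param detectability List: `efold_height` (m), `rate_scale`
#'   (calls h-1 per bird km-2 equivalent), `hours` (nightly recording
#'   hours), `dropout` (probability a night's recorder is down).
#' @param noise_v Velocity noise sd, m s-1 (isotropic Gaussian).
#' @param scan_interval_min Minutes between radar scans.
#' @param n_bins Number of 100 m altitude bins from the ground up.
#' @param rcs Radar cross section per bird, cm2.
#' @param seed Mandatory integer seed.
#' @return A `truth_params` list.
#' @export
truth_params <- function(season_start = "2019-08-01",
                         season_end = "2019-11-25",
                         total_passage = 50000,
                         peak_day = "2019-10-05",
                         passage_sd = 15,
                         night_sigma = 0.4,
                         jet = list(center_height = 1750, width = 500,
                                    direction = 225, speed = 8,
                                    ar_phi = 0.6, ar_sd = 0.15,
                                    day_factor = 0.25),
                         base_wind = list(speed = 2, direction = 225,
                                          period_days = 20, amp = 0.3),
                         bird = list(airspeed = 8, heading = 165,
                                     kappa = 50),
                         insect = list(airspeed = 1, eta_base = 5,
                                       scale_height = 2000, diel_amp = 0.3),
                         altitude = list(scale_height = 1200, kappa_w = 0),
                         detectability = list(efold_height = 1000,
                                              rate_scale = 2, hours = 10,
                                              dropout = 0.1),
                         noise_v = 0.5,
                         scan_interval_min = 30,
                         n_bins = 30,
                         rcs = 11,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(total_passage > 0, passage_sd > 0, night_sigma >= 0,
            jet$width > 0, bird$airspeed > insect$airspeed,
            altitude$scale_height > 0, n_bins >= 1, n_bins <= 50,
            noise_v >= 0)
  structure(list(season_start = as.Date(season_start),
                 season_end = as.Date(season_end),
                 total_passage = total_passage,
                 peak_day = as.Date(peak_day),
                 passage_sd = passage_sd, night_sigma = night_sigma,
                 jet = jet, base_wind = base_wind, bird = bird,
                 insect = insect, altitude = altitude,
                 detectability = detectability, noise_v = noise_v,
                 scan_interval_min = scan_interval_min, n_bins = n_bins,
                 rcs = rcs, seed = as.integer(seed)),
            class = "truth_params")
}

#' Packaged scenario presets
#'
#' `"tropical"`: weak base wind, stable jet, small night-effect sd (steady
#' passage). `"temperate"`: strong variable winds and a large night-effect sd
#' (episodic passage). `"noisefree"`: the tropical scenario with zero
#' velocity noise and no heading scatter, for exact forward-inverse checks.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [truth_params()] object.
#' @export
scenario_preset <- function(name = c("tropical", "temperate", "noisefree"),
                            seed = 1) {
  name <- match.arg(name)
  switch(name,
    tropical = truth_params(seed = seed),
    temperate = truth_params(
      night_sigma = 1.2,
      base_wind = list(speed = 6, direction = 150, period_days = 6,
                       amp = 0.8),
      jet = list(center_height = 1500, width = 600, direction = 160,
                 speed = 10, ar_phi = 0.3, ar_sd = 0.5, day_factor = 0.4),
      seed = seed),
    noisefree = truth_params(noise_v = 0, night_sigma = 0.4,
                             bird = list(airspeed = 8, heading = 165,
                                         kappa = Inf),
                             seed = seed))
}

# Standard-atmosphere geopotential height (m) of a pressure level (hPa).
.std_height <- function(p_hPa) {
  288.15 / 0.0065 * (1 - (p_hPa / 1013.25)^0.190284)
}

# Sample von Mises headings (degrees); Best-Fisher rejection sampling.
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa) || kappa > 1e6) return(rep(mu_deg %% 360, n))
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2 * (n - length(out)) + 8
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    fq <- (1 + r * z) / (r + z)
    cq <- kappa * (r - fq)
    acc <- (cq * (2 - cq) - u2 > 0) | (log(cq / u2) + 1 - cq >= 0)
    th <- sign(u3[acc] - 0.5) * acos(pmin(pmax(fq[acc], -1), 1))
    out <- c(out, th)
  }
  (mu_deg + out[seq_len(n)] * RAD2DEG) %% 360
}

# Night key used by the generator: local date shifted so one night (sunset to
# sunrise) shares a single key.
.gen_night_key <- function(time, station) {
  as.Date(time + station$utc_offset * 3600 - 12 * 3600, tz = "UTC")
}

#' Generate a synthetic atmospheric grid
#'
#' Three-hourly, 15 pressure levels from 1000 to 600 hPa. Wind is a slowly
#' varying base flow plus a Gaussian-in-altitude nocturnal low-level jet
#' whose nightly amplitude follows an AR(1) process; temperature follows a
#' fixed lapse, specific humidity decays with height, and omega/TKE carry
#' small correlated perturbations.
#'
#' @param params A [truth_params()].
#' @param station A [station_config()].
#' @return An `atmos_grid` object spanning the season (plus a one-day pad).
#' @export
gen_atmosphere <- function(params, station) {
  t0 <- as.POSIXct(paste(params$season_start - 1, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(params$season_end + 2, "00:00:00"), tz = "UTC")
  times <- seq(t0, t1, by = 3 * 3600)
  levels <- seq(1000, 600, length.out = 15)
  z <- .std_height(levels)
  nights <- .gen_night_key(times, station)
  night_ids <- sort(unique(nights))
  with_seed(params$seed + 7L, {
    # nightly AR(1) perturbation of the jet amplitude
    s <- numeric(length(night_ids))
    e <- stats::rnorm(length(night_ids), 0, params$jet$ar_sd)
    for (i in seq_along(s)) {
      s[i] <- if (i == 1) e[i] else params$jet$ar_phi * s[i - 1] + e[i]
    }
    jet_mult <- pmax(0, 1 + s)[match(nights, night_ids)]
    day_frac <- as.numeric(times - t0, units = "days")
    bw <- params$base_wind
    base_speed <- bw$speed *
      (1 + bw$amp * sin(2 * pi * day_frac / bw$period_days))
    diel <- ifelse(is_night(times, station$lat, station$lon),
                   1, params$jet$day_factor)
    grid <- expand.grid(time = times, level_hPa = levels,
                        KEEP.OUT.ATTRS = FALSE)
    it <- match(grid$time, times)
    zl <- z[match(grid$level_hPa, levels)]
    jet_speed <- params$jet$speed * jet_mult[it] * diel[it] *
      exp(-(zl - params$jet$center_height)^2 / (2 * params$jet$width^2))
    bvec <- uv_from_bearing(bw$direction)
    jvec <- uv_from_bearing(params$jet$direction)
    grid$gph_m <- zl
    grid$u <- base_speed[it] * bvec[, "u"] + jet_speed * jvec[, "u"]
    grid$v <- base_speed[it] * bvec[, "v"] + jet_speed * jvec[, "v"]
    hour_local <- (as.numeric(grid$time) / 3600 + station$utc_offset) %% 24
    grid$temp_K <- 298.15 - 0.0065 * zl +
      3 * exp(-zl / 1500) * cos(2 * pi * (hour_local - 15) / 24) +
      stats::rnorm(nrow(grid), 0, 0.3)
    grid$shum <- 0.016 * exp(-zl / 2500)
    grid$omega <- 0.05 * sin(2 * pi * day_frac[it] / 3) *
      exp(-zl / 3000) + stats::rnorm(nrow(grid), 0, 0.01)
    grid$tke <- pmax(0.01, 0.5 * jet_speed / max(params$jet$speed, 1) +
                       stats::rnorm(nrow(grid), 0, 0.05))
    as_atmos_grid(grid)
  })
}

#' Generate true nightly passage
#'
#' Nightly migration traffic proportional to a Gaussian seasonal curve times
#' mean-corrected lognormal night effects, normalized so the season total is
#' exactly `total_passage`. `night_sigma` is the episodicity knob: the
#' normalization keeps the season total fixed while larger sigma concentrates
#' passage into fewer nights.
#'
#' @param params A [truth_params()].
#' @return Data frame `night` (`Date`), `mt_true` (birds km-1).
#' @export
gen_truth_nights <- function(params) {
  nights <- seq(params$season_start, params$season_end, by = "day")
  w <- stats::dnorm(as.numeric(nights - params$peak_day) / params$passage_sd)
  mult <- with_seed(params$seed, {
    sig <- params$night_sigma
    stats::rlnorm(length(nights), meanlog = -sig^2 / 2, sdlog = sig)
  })
  raw <- w * mult
  data.frame(night = nights,
             mt_true = params$total_passage * raw / sum(raw))
}

#' Generate a synthetic profile time series with ground truth
#'
#' Forward model of the airspeed mixture: per scan, bird density is allocated
#' over altitude proportional to `exp(-height/scale) * exp(kappa_w *
#' tailwind)`, scaled so the time-integrated bird migration traffic of each
#' night equals its true nightly passage exactly; bird air velocity is the
#' fixed airspeed along a (possibly von Mises-scattered) preferred heading;
#' insect reflectivity drifts with the wind plus a 1 m s-1 downwind
#' self-propulsion; each bin's observed velocity is the exact
#' reflectivity-weighted mixture of the two ground velocities plus isotropic
#' Gaussian noise.
#'
#' @param truth Output of [gen_truth_nights()].
#' @param grid Output of [gen_atmosphere()].
#' @param params A [truth_params()].
#' @param station A [station_config()].
#' @return List: `series` (a `vpts`), `manifest` (list with per-bin truth
#'   `bins`, nightly truth `nights`, and `params`).
#' @export
gen_profiles <- function(truth, grid, params, station) {
  heights <- seq(0, by = BIN_WIDTH_M, length.out = params$n_bins)
  centres <- heights + BIN_WIDTH_M / 2
  a_b <- params$bird$airspeed
  a_i <- params$insect$airspeed
  scans <- lapply(seq_len(nrow(truth)), function(i) {
    nb <- night_bounds(truth$night[i], station)
    tt <- seq(nb$sunset + 300, nb$sunrise - 300,
              by = params$scan_interval_min * 60)
    data.frame(night = truth$night[i], datetime = tt,
               night_h = as.numeric(nb$sunrise - nb$sunset, units = "hours"))
  })
  scans <- do.call(rbind, scans)
  # wind at every (scan, bin) via the pipeline's own pairing
  skel <- as_vpts(data.frame(datetime = rep(scans$datetime,
                                            each = params$n_bins),
                             height = rep(heights, nrow(scans)),
                             eta = 0, u = NA_real_, v = NA_real_),
                  station)
  wx <- pair_weather(skel, grid)
  d <- skel$data[c("datetime", "height")]
  key <- paste(fmt_utc(d$datetime), d$height)
  wix <- match(key, paste(fmt_utc(wx$datetime), wx$height))
  uw <- wx$u_wind[wix]
  vw <- wx$v_wind[wix]
  six <- match(d$datetime, scans$datetime)

  with_seed(params$seed + 13L, {
    # bird heading and air velocity per bin
    hdg <- rvonmises_deg(nrow(d), params$bird$heading, params$bird$kappa)
    ub_air <- a_b * sin(hdg * DEG2RAD)
    vb_air <- a_b * cos(hdg * DEG2RAD)
    ub <- ub_air + uw
    vb <- vb_air + vw
    # altitude allocation: exponential profile x tailwind preference
    pref <- uv_from_bearing(params$bird$heading)
    tw <- uw * pref[, "u"] + vw * pref[, "v"]
    shape <- exp(-(d$height - station$height_m) /
                   params$altitude$scale_height) *
      exp(params$altitude$kappa_w * tw)
    g_kmh <- speed_kmh(ub, vb)
    # per-scan density scale so bird MTR equals the night's constant target
    mtr_target <- (truth$mt_true / scans$night_h[match(truth$night,
                                                       scans$night)])
    mtr_target <- mtr_target[match(scans$night[six], truth$night)]
    denom <- tapply(shape * g_kmh * DELTA_H_KM, six, sum)[as.character(six)]
    dens_b <- shape * mtr_target / as.numeric(denom)
    eta_b <- dens_b * params$rcs
    # insects: background reflectivity drifting downwind
    frac_night <- (as.numeric(d$datetime) -
                     as.numeric(tapply(as.numeric(d$datetime), six, min)[
                       as.character(six)])) /
      pmax(1, scans$night_h[six] * 3600)
    eta_i <- params$insect$eta_base *
      exp(-d$height / params$insect$scale_height) *
      (1 + params$insect$diel_amp * sin(pi * pmin(frac_night, 1)))
    wspd <- sqrt(uw^2 + vw^2)
    calm <- wspd < partition_params()$calm_wind_eps
    ui <- uw + ifelse(calm, 0, a_i * uw / wspd)
    vi <- vw + ifelse(calm, 0, a_i * vw / wspd)
    eta_tot <- eta_b + eta_i
    f_true <- ifelse(eta_tot > 0, eta_b / eta_tot, NA_real_)
    u_obs <- ifelse(eta_tot > 0, (eta_b * ub + eta_i * ui) / eta_tot,
                    NA_real_) + stats::rnorm(nrow(d), 0, params$noise_v)
    v_obs <- ifelse(eta_tot > 0, (eta_b * vb + eta_i * vi) / eta_tot,
                    NA_real_) + stats::rnorm(nrow(d), 0, params$noise_v)
    series <- as_vpts(data.frame(datetime = d$datetime, height = d$height,
                                 eta = eta_tot, u = u_obs, v = v_obs),
                      station)
    manifest <- list(
      bins = data.frame(datetime = d$datetime, height = d$height,
                        f_true = f_true, heading_true = hdg,
                        eta_bird_true = eta_b, eta_insect_true = eta_i,
                        u_wind = uw, v_wind = vw),
      nights = truth,
      params = params)
    list(series = series, manifest = manifest)
  })
}

#' Generate nightly acoustic recording logs
#'
#' Call counts are Poisson with a rate proportional to the bird density
#' column weighted by an exponentially height-decaying detectability, so
#' lower-flying migration yields more calls for the same aerial density.
#' Recorder dropout removes whole nights.
#'
#' @param profiles Output of [gen_profiles()].
#' @param params A [truth_params()].
#' @param station A [station_config()].
#' @return Data frame `night`, `taxon`, `calls`, `hours` (two synthetic
#'   taxa), plus attribute `rate_true` (expected calls h-1 per night).
#' @export
gen_calls <- function(profiles, params, station) {
  man <- profiles$manifest$bins
  det <- params$detectability
  man$dens_b <- man$eta_bird_true / params$rcs
  wdet <- exp(-(man$height + BIN_WIDTH_M / 2) / det$efold_height)
  nightkey <- assign_night(man$datetime, station)
  agg <- stats::aggregate(
    list(idx = man$dens_b * wdet * DELTA_H_KM),
    by = list(night = nightkey, datetime = man$datetime), FUN = sum)
  rate <- stats::aggregate(list(rate = agg$idx), by = list(night = agg$night),
                           FUN = mean)
  rate$rate <- det$rate_scale * rate$rate
  with_seed(params$seed + 29L, {
    up <- stats::runif(nrow(rate))
    keep <- up >= det$dropout
    counts <- stats::rpois(nrow(rate), rate$rate * det$hours)
    split1 <- stats::rbinom(nrow(rate), counts, 0.7)
    out <- rbind(
      data.frame(night = rate$night, taxon = "thrush", calls = split1,
                 hours = det$hours),
      data.frame(night = rate$night, taxon = "warbler",
                 calls = counts - split1, hours = det$hours))
    out <- out[out$night %in% rate$night[keep], , drop = FALSE]
    out <- out[order(out$night, out$taxon), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rate_true") <- stats::setNames(rate$rate,
                                              format(rate$night))
    out
  })
}
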