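# Shared fixtures, built in code at test time.

fix_station <- function() station_config("BAR", 6.9325, -73.7625, 80)

# Minimal two-profile series with one velocity-missing bin.
fix_series <- function(station = fix_station()) {
  as_vpts(data.frame(
    datetime = rep(c("2019-10-01T01:00:00Z", "2019-10-01T02:00:00Z"),
                   each = 3),
    height = rep(c(0, 100, 200), 2),
    eta = c(11, 22, 0, 5.5, 11, 2.2),
    u = c(1, 2, NA, 0.5, NA, 1),
    v = c(0.5, -1, NA, 0.25, NA, 2)), station)
}

# Atmosphere grid with a field linear in time and height (plus constants),
# two levels with fixed geopotential heights.
fix_grid_linear <- function(a = 2, b = 4, cc = 0.003,
                            t0 = "2019-10-01T00:00:00Z", n_times = 4,
                            gph = c(100, 1500)) {
  times <- as.POSIXct(t0, tz = "UTC") + 3 * 3600 * (seq_len(n_times) - 1)
  g <- expand.grid(time = times, level_hPa = c(1000, 850))
  g$gph_m <- gph[match(g$level_hPa, c(1000, 850))]
  th <- as.numeric(g$time - times[1], units = "hours")
  lin <- a + b * th + cc * g$gph_m
  g$u <- lin
  g$v <- -lin
  g$temp_K <- 288 + 0 * lin
  g$shum <- 0.01
  g$omega <- lin / 100
  g$tke <- 0.2
  as_atmos_grid(g)
}

# Small deterministic nightly-traffic season.
fix_nightly <- function(mt, start = "2019-09-01") {
  data.frame(night = as.Date(start) + seq_along(mt) - 1, mt_night = mt,
             mean_mtr = mt / 10, n_scans = 10L, gap_flag = FALSE)
}

# Cache for expensive synthetic scenarios shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

fix_scenario <- function(preset, seed) {
  key <- paste(preset, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    st <- fix_station()
    params <- scenario_preset(preset, seed = seed)
    grid <- gen_atmosphere(params, st)
    truth <- gen_truth_nights(params)
    prof <- gen_profiles(truth, grid, params, st)
    .fixture_cache[[key]] <- list(station = st, params = params,
                                  grid = grid, truth = truth,
                                  series = prof$series,
                                  manifest = prof$manifest)
  }
  .fixture_cache[[key]]
}

# Independent per-night statistics used as oracles for phenology.
oracle_pct_nights <- function(mt, fraction) {
  total <- sum(mt)
  n <- length(mt)
  for (k in seq_len(n)) {
    best <- 0
    for (set in utils::combn(n, k, simplify = FALSE)) {
      best <- max(best, sum(mt[set]))
    }
    if (best >= fraction * total - 1e-9 * total) return(100 * k / n)
  }
  100
}

oracle_crossing_date <- function(night, mt, frac) {
  o <- order(night)
  cum <- cumsum(mt[o])
  night[o][which(cum >= frac * sum(mt) - 1e-9 * sum(mt))[1]]
}
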