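test_that("generated atmosphere has jet structure and valid geometry", {
  st <- fix_station()
  p <- truth_params(seed = 61, season_start = "2019-09-01",
                    season_end = "2019-09-20")
  grid <- gen_atmosphere(p, st)
  gd <- grid$data
  expect_equal(length(grid$levels), 15)
  expect_equal(range(grid$levels), c(600, 1000))
  # gph strictly increasing within each time
  expect_true(all(tapply(gd$gph_m, format(gd$time), function(z)
    all(diff(z) > 0))))
  # nocturnal wind speed peaks near the jet centre
  night_rows <- is_night(gd$time, st$lat, st$lon)
  spd <- sqrt(gd$u^2 + gd$v^2)
  by_z <- tapply(spd[night_rows], gd$gph_m[night_rows], mean)
  zs <- as.numeric(names(by_z))
  z_peak <- zs[which.max(by_z)]
  expect_lt(abs(z_peak - p$jet$center_height), p$jet$width)
  far <- abs(zs - p$jet$center_height) > 2 * p$jet$width
  expect_gt(max(by_z), max(by_z[far]))
  # zero jet speed leaves only the base wind (no altitude structure)
  p0 <- truth_params(seed = 61, season_start = "2019-09-01",
                     season_end = "2019-09-20",
                     jet = list(center_height = 1750, width = 500,
                                direction = 135, speed = 0, ar_phi = 0,
                                ar_sd = 0, day_factor = 1))
  g0 <- gen_atmosphere(p0, st)
  spd0 <- sqrt(g0$data$u^2 + g0$data$v^2)
  expect_equal(as.numeric(tapply(spd0, format(g0$data$time), sd)),
               rep(0, length(g0$times)), tolerance = 1e-9)
})

test_that("nightly jet perturbations decorrelate when phi = 0", {
  st <- fix_station()
  p <- truth_params(seed = 62, season_start = "2019-01-01",
                    season_end = "2020-05-15",
                    base_wind = list(speed = 0, direction = 120,
                                     period_days = 20, amp = 0),
                    jet = list(center_height = 1750, width = 500,
                               direction = 135, speed = 8, ar_phi = 0,
                               ar_sd = 0.15, day_factor = 1))
  grid <- gen_atmosphere(p, st)
  z_near <- unique(grid$data$gph_m)
  z_near <- z_near[which.min(abs(z_near - 1750))]
  gd <- grid$data[grid$data$gph_m == z_near, ]
  # recover the nightly multiplier from the 06:00 UTC (01:00 local) rows
  rows <- format(gd$time, "%H") == "06"
  spd <- sqrt(gd$u[rows]^2 + gd$v[rows]^2)
  ac <- stats::acf(spd, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 0.15)
})

test_that("true nightly passage is normalized and sigma-responsive", {
  p0 <- truth_params(night_sigma = 0, seed = 63)
  tr0 <- gen_truth_nights(p0)
  expect_equal(sum(tr0$mt_true), p0$total_passage)
  # no night noise: smooth Gaussian staircase, near-deterministic pct-nights
  w <- dnorm(as.numeric(tr0$night - p0$peak_day) / p0$passage_sd)
  expect_equal(tr0$mt_true, p0$total_passage * w / sum(w), tolerance = 1e-12)
  det50 <- pct_nights(tr0$mt_true, 0.5)
  p1 <- truth_params(night_sigma = 1.5, seed = 63)
  tr1 <- gen_truth_nights(p1)
  expect_equal(sum(tr1$mt_true), p1$total_passage)
  expect_lt(pct_nights(tr1$mt_true, 0.5), det50)
  expect_gt(season_cv(tr1$mt_true), season_cv(tr0$mt_true))
})

test_that("generator mixture bookkeeping is exact before noise", {
  sc <- fix_scenario("noisefree", seed = 64)
  man <- sc$manifest$bins
  d <- sc$series$data
  expect_equal(d$eta, man$eta_bird_true + man$eta_insect_true,
               tolerance = 1e-12)
  # observed velocity is exactly the reflectivity-weighted mixture
  ai <- sc$params$insect$airspeed
  wsp <- sqrt(man$u_wind^2 + man$v_wind^2)
  wu <- ifelse(wsp < 0.5, 0, man$u_wind / wsp)
  wv <- ifelse(wsp < 0.5, 0, man$v_wind / wsp)
  hb <- man$heading_true * pi / 180
  ub <- sc$params$bird$airspeed * sin(hb) + man$u_wind
  vb <- sc$params$bird$airspeed * cos(hb) + man$v_wind
  f <- man$f_true
  expect_equal(d$u, f * ub + (1 - f) * (man$u_wind + ai * wu),
               tolerance = 1e-10)
  expect_equal(d$v, f * vb + (1 - f) * (man$v_wind + ai * wv),
               tolerance = 1e-10)
})

test_that("generation is bit-reproducible for identical parameters", {
  st <- fix_station()
  p <- truth_params(seed = 65, season_start = "2019-10-01",
                    season_end = "2019-10-10")
  g1 <- gen_atmosphere(p, st); g2 <- gen_atmosphere(p, st)
  expect_identical(g1, g2)
  t1 <- gen_truth_nights(p); t2 <- gen_truth_nights(p)
  expect_identical(t1, t2)
  pr1 <- gen_profiles(t1, g1, p, st); pr2 <- gen_profiles(t2, g2, p, st)
  expect_identical(pr1, pr2)
  expect_identical(gen_calls(pr1, p, st), gen_calls(pr2, p, st))
})

test_that("pure-bird scenarios show the bird airspeed everywhere occupied", {
  st <- fix_station()
  p <- truth_params(seed = 66, season_start = "2019-10-01",
                    season_end = "2019-10-05", noise_v = 0,
                    bird = list(airspeed = 8, heading = 165, kappa = Inf),
                    insect = list(airspeed = 1, eta_base = 0,
                                  scale_height = 2000, diel_amp = 0))
  tr <- gen_truth_nights(p)
  pr <- gen_profiles(tr, gen_atmosphere(p, st), p, st)
  d <- pr$series$data
  occ <- d$eta > 0
  man <- pr$manifest$bins
  aspd <- sqrt((d$u - man$u_wind)^2 + (d$v - man$v_wind)^2)
  expect_equal(aspd[occ], rep(8, sum(occ)), tolerance = 1e-9)
  expect_equal(man$f_true[occ], rep(1, sum(occ)))
})

test_that("tailwind altitude preference raises mean flight height", {
  st <- fix_station()
  mk <- function(kw) {
    truth_params(seed = 67, season_start = "2019-10-01",
                 season_end = "2019-10-08", noise_v = 0,
                 altitude = list(scale_height = 1200, kappa_w = kw))
  }
  heights <- sapply(c(0, 0.4), function(kw) {
    p <- mk(kw)
    pr <- gen_profiles(gen_truth_nights(p), gen_atmosphere(p, st), p, st)
    mean(integrate_profile(pr$series)$mean_height)
  })
  # fall jet blows toward the preferred direction: kappa_w > 0 pulls birds
  # into the faster high-tailwind layer near the jet
  expect_gt(heights[2], heights[1])
})

test_that("call counts track height-weighted density with Poisson noise", {
  sc <- fix_scenario("tropical", seed = 68)
  calls <- gen_calls(list(manifest = sc$manifest), sc$params, sc$station)
  expect_true(all(c("night", "taxon", "calls", "hours") %in% names(calls)))
  expect_true(all(calls$calls >= 0) && all(calls$hours > 0))
  rate_true <- attr(calls, "rate_true")
  rates <- call_rate(calls)
  both <- intersect(format(rates$night), names(rate_true))
  expect_gt(cor(rates$call_rate[match(both, format(rates$night))],
                rate_true[both]), 0.85)
  # Poisson mean recovery on repeated nights at a fixed analytic rate
  p <- sc$params
  lam <- max(rate_true) * p$detectability$hours
  set.seed(69)
  draws <- rpois(1000, lam)
  expect_lt(abs(mean(draws) - lam), 3 * sqrt(lam / 1000))
  # zero passage means zero expected calls
  expect_equal(sum(rate_true[rate_true < 1e-9]), 0)
})
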