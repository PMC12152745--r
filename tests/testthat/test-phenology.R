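test_that("nightly integration uses clipped midpoint weights", {
  st <- fix_station()
  nb <- night_bounds("2019-10-01", st)
  night_h <- as.numeric(nb$sunrise - nb$sunset, units = "hours")
  # constant MTR over the whole night integrates to MTR x night length
  ts <- seq(nb$sunset + 60, nb$sunrise - 60, by = 1800)
  sc <- data.frame(datetime = ts, mtr = 100,
                   night = as.Date("2019-10-01"))
  ns <- nightly_summaries(sc, st)
  expect_equal(ns$mt_night, 100 * night_h, tolerance = 1e-9)
  expect_equal(ns$mean_mtr, 100)
  expect_false(ns$gap_flag)
  # two scans with equal sub-intervals time-weight to the plain mean
  mid <- nb$sunset + (nb$sunrise - nb$sunset) / 2
  sc2 <- data.frame(datetime = c(mid - 3600, mid + 3600), mtr = c(50, 150),
                    night = as.Date("2019-10-01"))
  ns2 <- nightly_summaries(sc2, st)
  expect_equal(ns2$mean_mtr, 100)
  expect_equal(ns2$mt_night, 100 * night_h)
  # a 3 h hole in usable MTR flags the night
  ts3 <- ts[!(ts > nb$sunset + 2 * 3600 & ts < nb$sunset + 5.2 * 3600)]
  ns3 <- nightly_summaries(data.frame(datetime = ts3, mtr = 100,
                                      night = as.Date("2019-10-01")), st)
  expect_true(ns3$gap_flag)
  # all-missing MTR yields missing summaries
  ns4 <- nightly_summaries(data.frame(datetime = ts, mtr = NA_real_,
                                      night = as.Date("2019-10-01")), st)
  expect_true(is.na(ns4$mean_mtr) && is.na(ns4$mt_night) && ns4$gap_flag)
})

test_that("season CV is the sample-sd coefficient of variation", {
  expect_equal(season_cv(c(5, 5, 5)), 0)
  expect_equal(season_cv(c(2, 4)), sqrt(2) / 3)
  expect_error(season_cv(5), ">= 2 nights")
  expect_error(season_cv(c(0, 0)), "zero")
  # lognormal night effects: bigger sigma, bigger CV
  set.seed(41)
  lo <- rlnorm(90, -0.3^2 / 2, 0.3)
  hi <- rlnorm(90, -1 / 2, 1)
  expect_gt(season_cv(hi), season_cv(lo))
})

test_that("bootstrap is seed-deterministic with percentile intervals", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  b1 <- bootstrap_stat(x, "mean", n_rep = 500, seed = 99)
  b2 <- bootstrap_stat(x, "mean", n_rep = 500, seed = 99)
  expect_identical(b1, b2)
  expect_equal(b1$estimate, mean(x))
  expect_true(b1$lo <= b1$estimate && b1$estimate <= b1$hi)
  # constant input gives a zero-width interval
  bc <- bootstrap_stat(rep(4, 6), "mean", n_rep = 100, seed = 1)
  expect_equal(unlist(bc), c(estimate = 4, lo = 4, hi = 4))
  # cv statistic runs and brackets its point estimate for well-behaved data
  set.seed(42)
  y <- rlnorm(60, 0, 0.5)
  bcv <- bootstrap_stat(y, "cv", n_rep = 1000, seed = 7)
  expect_true(bcv$lo < bcv$hi)
  # the bootstrap does not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(bootstrap_stat(x, "mean", n_rep = 50, seed = 5))
  expect_identical(runif(1), r1)
})

test_that("percent-of-nights matches subset enumeration", {
  expect_equal(pct_nights(rep(3, 10), 0.5), 50)
  expect_equal(pct_nights(c(10, 0, 0, 0), 0.5), 25)
  expect_equal(pct_nights(c(8, 4, 2, 1, 1), 0.5), 20)
  expect_error(pct_nights(c(0, 0), 0.5), "all-zero")
  set.seed(43)
  for (i in 1:12) {
    mt <- round(rexp(sample(4:10, 1), 1 / 50), 1)
    for (fr in c(0.5, 0.75, 0.9)) {
      expect_equal(pct_nights(mt, fr), oracle_pct_nights(mt, fr))
    }
  }
})

test_that("percent-of-nights is monotone in the fraction", {
  set.seed(44)
  for (i in 1:20) {
    mt <- rexp(30)
    ps <- vapply(c(0.5, 0.75, 0.9), function(f) pct_nights(mt, f),
                 numeric(1))
    expect_true(all(diff(ps) >= 0))
  }
  # single-spike and uniform closed forms
  expect_equal(pct_nights(c(0.001, 50, 0.001, 0.001), 0.9), 25)
  expect_equal(pct_nights(rep(1, 8), 0.75), 100 * ceiling(0.75 * 8) / 8)
})

test_that("core spans and peak dates follow the crossing rules", {
  nights <- as.Date("2019-09-01") + 0:9
  expect_equal(core_span(nights, rep(5, 10), 0.2, 0.8), 6)
  expect_equal(core_span(nights, rep(5, 10), 0.1, 0.9), 8)
  expect_equal(core_span(nights, c(100, rep(0, 9)), 0.2, 0.8), 0)
  # symmetric triangle peaks in the middle
  tri <- c(1:11, 10:1)
  nights21 <- as.Date("2019-09-01") + 0:20
  expect_equal(peak_date(nights21, tri), nights21[11])
  expect_equal(peak_date(nights, c(100, rep(0, 9))), nights[1])
  # random seasons against the direct crossing oracle
  set.seed(45)
  for (i in 1:50) {
    mt <- rexp(sample(5:25, 1))
    ns <- as.Date("2019-08-01") + seq_along(mt) - 1
    shuf <- sample(length(mt))
    expect_equal(peak_date(ns[shuf], mt[shuf]),
                 oracle_crossing_date(ns, mt, 0.5))
    expect_equal(core_span(ns[shuf], mt[shuf], 0.2, 0.8),
                 as.numeric(oracle_crossing_date(ns, mt, 0.8) -
                              oracle_crossing_date(ns, mt, 0.2)))
    expect_gte(core_span(ns, mt, 0.1, 0.9), core_span(ns, mt, 0.2, 0.8))
  }
})

test_that("cumulative curve is a normalized non-decreasing staircase", {
  nights <- as.Date("2019-09-01") + 0:9
  cc <- cumulative_curve(nights, rep(2, 10))
  expect_equal(cc$cum_fraction, seq(0.1, 1, by = 0.1))
  set.seed(46)
  mt <- rexp(40)
  cc2 <- cumulative_curve(as.Date("2019-08-01") + 0:39, mt)
  expect_true(all(diff(cc2$cum_fraction) >= 0))
  expect_equal(cc2$cum_fraction[40], 1, tolerance = 1e-12)
  expect_equal(diff(c(0, cc2$cum_fraction)), mt / sum(mt))
})

test_that("episodicity statistics move with the night-effect sd", {
  sigmas <- c(0.25, 0.5, 1.0, 1.5)
  cvs <- pct50 <- numeric(length(sigmas))
  for (i in seq_along(sigmas)) {
    acc_cv <- acc_p <- 0
    for (seed in 1:8) {
      p <- truth_params(night_sigma = sigmas[i], seed = seed,
                        season_start = "2019-08-15",
                        season_end = "2019-11-12")
      tr <- gen_truth_nights(p)
      acc_cv <- acc_cv + season_cv(tr$mt_true)
      acc_p <- acc_p + pct_nights(tr$mt_true, 0.5)
    }
    cvs[i] <- acc_cv / 8
    pct50[i] <- acc_p / 8
  }
  expect_true(all(diff(cvs) > 0))
  expect_true(all(diff(pct50) < 0))
})
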