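test_that("two-stage interpolation matches the hand-computed fixture", {
  # level heights 0 and 900 m; level-1 series (10, 16) and level-2 series
  # (18, 24) over 00:00 -> 03:00 give (12, 20) at 01:00; the 400 m bin's
  # centre (450 m, the level midpoint) then interpolates to 16.0
  times <- as.POSIXct(c("2019-10-01 00:00", "2019-10-01 03:00"), tz = "UTC")
  g <- expand.grid(time = times, level_hPa = c(1000, 850))
  g$gph_m <- c(0, 0, 900, 900)
  g$u <- c(10, 16, 18, 24)
  g$v <- 0; g$temp_K <- 288; g$shum <- 0.01; g$omega <- 0; g$tke <- 0.1
  grid <- as_atmos_grid(g)
  s <- as_vpts(data.frame(datetime = "2019-10-01T01:00:00Z", height = 400,
                          eta = 11, u = 0, v = 1), fix_station())
  paired <- pair_weather(s, grid)
  expect_equal(paired$u_wind, 16.0)
})

test_that("a constant field pairs to that constant everywhere", {
  grid <- fix_grid_linear(a = 5, b = 0, cc = 0)
  s <- fix_series()
  paired <- pair_weather(s, grid)
  expect_equal(paired$u_wind, rep(5, 6))
  expect_equal(paired$temp, rep(288, 6))
})

test_that("jointly linear fields are reproduced exactly at bin centres", {
  a <- 2; b <- 4; cc <- 0.003
  grid <- fix_grid_linear(a, b, cc)
  st <- fix_station()
  hts <- seq(100, 1300, by = 100)  # centres 150..1350, inside 100..1500 m
  s <- as_vpts(data.frame(
    datetime = rep(c("2019-10-01T01:17:00Z", "2019-10-01T07:45:00Z"),
                   each = length(hts)),
    height = rep(hts, 2), eta = 11, u = 0, v = 1), st)
  paired <- pair_weather(s, grid)
  th <- as.numeric(paired$datetime -
                     as.POSIXct("2019-10-01 00:00", tz = "UTC"),
                   units = "hours")
  want <- a + b * th + cc * (paired$height + 50)
  expect_equal(paired$u_wind, want, tolerance = 1e-9)
  expect_equal(paired$v_wind, -want, tolerance = 1e-9)
  expect_equal(paired$omega, want / 100, tolerance = 1e-9)
})

test_that("values clamp to the nearest level outside the height span", {
  grid <- fix_grid_linear(a = 1, b = 0, cc = 0.01, gph = c(500, 1000))
  st <- fix_station()
  s <- as_vpts(data.frame(datetime = rep("2019-10-01T03:00:00Z", 2),
                          height = c(0, 2000), eta = 11, u = 0, v = 1), st)
  paired <- pair_weather(s, grid)
  expect_equal(paired$u_wind, c(1 + 0.01 * 500, 1 + 0.01 * 1000))
})

test_that("timestamps outside the grid span yield missing values", {
  grid <- fix_grid_linear(n_times = 2)
  st <- fix_station()
  s <- as_vpts(data.frame(datetime = c("2019-10-01T01:00:00Z",
                                       "2019-10-02T01:00:00Z"),
                          height = 100, eta = 11, u = 0, v = 1), st)
  expect_warning(paired <- pair_weather(s, grid), "outside")
  expect_false(is.na(paired$u_wind[1]))
  expect_true(is.na(paired$u_wind[2]))
  expect_equal(paired$in_span, c(TRUE, FALSE))
})

test_that("flow assistance follows the EQ-airspeed closed form", {
  expect_equal(tailwind_eq_airspeed(0, 0, 0), 0)
  expect_equal(tailwind_eq_airspeed(0, 5, 0), 5)        # pure tailwind
  expect_equal(tailwind_eq_airspeed(5, 0, 0), sqrt(39) - 8)
  expect_true(is.na(tailwind_eq_airspeed(9, 0, 0)))     # infeasible
  # vector oracle: rotate heading to cancel crosswind; assistance is the
  # ground-speed gain along the preferred direction
  set.seed(3)
  for (i in 1:50) {
    uw <- rnorm(1, 0, 4); vw <- rnorm(1, 0, 4); pd <- runif(1, 0, 360)
    a <- 8
    th <- pd * pi / 180
    tw <- uw * sin(th) + vw * cos(th)
    cw <- uw * cos(th) - vw * sin(th)
    got <- tailwind_eq_airspeed(uw, vw, pd, a)
    if (abs(cw) > a) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, tw + sqrt(a^2 - cw^2) - a, tolerance = 1e-12)
      # never exceeds the wind speed itself
      expect_lte(got, sqrt(uw^2 + vw^2) + 1e-12)
    }
  }
})

test_that("flow assistance decreases with crosswind at fixed tailwind", {
  cw <- seq(0, 7.9, by = 0.5)
  vals <- tailwind_eq_airspeed(cw, 3, 0)  # pd = 0: v is tail, u is cross
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 3)
})

test_that("preferred direction is a weighted circular mean", {
  expect_equal(preferred_direction(rep(45, 5), runif(5, 1, 2)), 45)
  expect_equal(preferred_direction(c(350, 10), c(1, 1)), 0)
  expect_equal(preferred_direction(c(0, 90), c(3, 1)),
               atan2(1, 3) * 180 / pi)
  # invariant under weight scaling and global rotation
  set.seed(4)
  tr <- runif(20, 0, 360); w <- rexp(20)
  p0 <- preferred_direction(tr, w)
  expect_equal(preferred_direction(tr, 7 * w), p0)
  for (delta in c(30, 123, 300)) {
    expect_equal(preferred_direction((tr + delta) %% 360, w),
                 (p0 + delta) %% 360, tolerance = 1e-9)
  }
  expect_error(preferred_direction(numeric(0), numeric(0)), "no bins")
})

test_that("ground-level values come from the bin centre nearest the ground", {
  st <- fix_station()  # 80 m a.s.l.
  paired <- data.frame(
    datetime = as.POSIXct(rep("2019-10-01 01:00", 3), tz = "UTC"),
    height = c(0, 100, 200), u_wind = 0, v_wind = 0,
    temp = c(300, 299, 298), shum = 0.01, omega = 0, tke = 0.1)
  got <- ground_level_value(paired, "temp", st)
  expect_equal(got$height, 0)  # centre 50 m is nearest 80 m
  expect_equal(got$temp, 300)
  # ties resolve to the lower bin: station ground exactly between centres
  st2 <- station_config("X", 5, -73, 100)
  got2 <- ground_level_value(paired, "temp", st2)
  expect_equal(got2$height, 0)
  # single-bin profile returns that bin
  got3 <- ground_level_value(paired[2, ], "temp", st)
  expect_equal(got3$height, 100)
})

test_that("collinearity screen drops lower-priority collinear members", {
  set.seed(5)
  x <- rnorm(1000)
  tab <- data.frame(x = x, y = 2 * x, z = rnorm(1000))
  expect_equal(collinearity_screen(tab, priority = c("x", "y", "z")),
               c("x", "z"))
  # independent standard-normal columns are all retained
  tab2 <- as.data.frame(matrix(rnorm(5000), ncol = 5))
  expect_equal(collinearity_screen(tab2), names(tab2))
  # three mutually correlated columns leave exactly the top-priority one
  base <- rnorm(500)
  tab3 <- data.frame(a = base + rnorm(500, 0, 0.1),
                     b = base + rnorm(500, 0, 0.1),
                     c = base + rnorm(500, 0, 0.1))
  expect_equal(collinearity_screen(tab3, priority = c("b", "a", "c")), "b")
  # constant column excluded with a warning
  tab4 <- data.frame(x = x, y = 2 * x, k = rep(1, 1000))
  expect_warning(keep <- collinearity_screen(tab4), "constant")
  expect_equal(keep, "x")
})

test_that("wind MAD is a symmetric mean absolute difference", {
  expect_equal(wind_mad(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wind_mad(c(3, 7), c(5, 5)), 2)
  expect_equal(wind_mad(c(3, 7), c(5, 5)), wind_mad(c(5, 5), c(3, 7)))
  expect_error(wind_mad(NA_real_, 1), "zero matched")
})
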