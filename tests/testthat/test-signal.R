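test_that("VeDBA is zero for a static posture and invariant to axis offsets", {
  t <- (0:999) / 50
  acc <- tibble::tibble(t = t, ax = 0, ay = 0, az = 1)
  expect_equal(vedba_series(acc)$vedba, rep(0, 1000))
  # constant offsets are absorbed into the static component everywhere
  withr::with_seed(1, {
    acc2 <- tibble::tibble(t = t, ax = rnorm(1000, 0, 0.1),
                           ay = rnorm(1000, 0, 0.1),
                           az = 1 + rnorm(1000, 0, 0.1))
  })
  v1 <- vedba_series(acc2)$vedba
  acc3 <- dplyr::mutate(acc2, ax = ax + 0.3, ay = ay - 0.2, az = az + 1.1)
  expect_equal(vedba_series(acc3)$vedba, v1, tolerance = 1e-12)
  expect_true(all(v1 >= 0))
})

test_that("VeDBA of a sinusoidal heave recovers the rectified-sine mean 2A/pi", {
  fs <- 200 # fine sampling so discretization does not mask window leakage
  t <- (0:(fs * 60 - 1)) / fs
  acc <- tibble::tibble(t = t, ax = 0, ay = 0,
                        az = 1 + 0.5 * sin(2 * pi * 5 * t))
  v <- vedba_series(acc)
  interior <- v$vedba[(2 * fs + 1):(52 * fs)] # whole rectified periods
  expect_equal(mean(interior), 2 * 0.5 / pi, tolerance = 0.02)
})

test_that("VeDBA is invariant under axis relabelling and flags bad input", {
  withr::with_seed(2, {
    t <- (0:499) / 50
    acc <- tibble::tibble(t = t, ax = rnorm(500, 0, 0.2),
                          ay = rnorm(500, 1, 0.2), az = rnorm(500, 0.5, 0.2))
  })
  v1 <- vedba_series(acc)$vedba
  v2 <- vedba_series(dplyr::rename(acc, ax = az, az = ax))$vedba
  expect_equal(v2, v1)
  bad <- acc
  bad$t[10] <- bad$t[12] # non-monotone at index 11
  expect_error(vedba_series(bad), "index 11")
})

test_that("smoothing and summation conserve totals and bin correctly", {
  t <- (0:(50 * 60 * 3 - 1)) / 50
  sm <- smooth_and_sum(rep(0.5, length(t)), t)
  expect_equal(nrow(sm), 3)
  expect_equal(sm$dba, rep(60 * 0.5, 3))
  expect_false(any(sm$partial))
  one <- smooth_and_sum(rep(1, 50 * 60), (0:(50 * 60 - 1)) / 50)
  expect_equal(nrow(one), 1)
  withr::with_seed(3, v <- rexp(50 * 60 * 5))
  tt <- (seq_along(v) - 1) / 50
  sec <- vedba_seconds(v, tt)
  sm2 <- smooth_and_sum(v, tt)
  expect_equal(sum(sm2$dba), sum(sec$vedba_1s), tolerance = 1e-9)
  # partial minute flagged
  sm3 <- smooth_and_sum(rep(1, 50 * 90), (0:(50 * 90 - 1)) / 50)
  expect_true(sm3$partial[2])
})

test_that("wingbeat FFT finds single tones, prefers the larger peak, and flags flat windows", {
  t <- (0:1499) / 50
  expect_equal(wingbeat_frequency(sin(2 * pi * 5 * t))$freq_hz, 5,
               tolerance = 1 / 30)
  two <- sin(2 * pi * 3 * t) + 2 * sin(2 * pi * 7 * t)
  expect_equal(wingbeat_frequency(two)$freq_hz, 7, tolerance = 1 / 30)
  flat <- wingbeat_frequency(rep(1, 1500))
  expect_equal(flat$freq_hz, 0)
  expect_true(flat$flat)
})

test_that("white-noise peak frequencies are uniform over bins", {
  withr::with_seed(4, z <- rnorm(1500 * 1000))
  wf <- wingbeat_frequency(z, stride_s = 30)
  expect_equal(nrow(wf), 1000)
  bins <- round(wf$freq_hz * 30)
  # chi-square goodness of fit against the flat spectrum, 10 bin groups
  grp <- cut(bins, breaks = seq(0.5, 750.5, length.out = 11))
  cs <- suppressWarnings(stats::chisq.test(table(grp)))
  expect_gt(cs$p.value, 0.001)
})

test_that("dive fraction reproduces the worked threshold examples", {
  d30 <- tibble::tibble(t = 0:59, depth_m = c(rep(2, 30), rep(0, 30)))
  expect_equal(dive_fraction(d30)$dive_frac, 0.5)
  dry <- tibble::tibble(t = 0:59, depth_m = rep(0, 60))
  expect_equal(dive_fraction(dry)$dive_frac, 0)
  wet <- tibble::tibble(t = 0:59, depth_m = rep(3, 60))
  expect_equal(dive_fraction(wet)$dive_frac, 1)
  expect_warning(dive_fraction(tibble::tibble(t = 0:59, depth_m = rep(-2, 60))),
                 "Negative")
})

test_that("track interpolation hits the 1-min grid and recovers linear motion", {
  gps <- tibble::tibble(t = c(0, 60, 180), lon = c(0, 0.01, 0.03),
                        lat = c(0, 0.01, 0.03)) # constant velocity, one gap
  tr <- interpolate_track(gps)
  expect_equal(diff(tr$t), rep(60, nrow(tr) - 1))
  expect_equal(tr$lon[tr$t == 120], 0.02) # midpoint recovered exactly
  stat <- interpolate_track(tibble::tibble(t = c(0, 65, 118), lon = 1, lat = 2))
  expect_true(all(stat$lon == 1) && all(stat$lat == 2))
  expect_error(interpolate_track(tibble::tibble(t = 0, lon = 1, lat = 2)),
               ">= 2")
  gap <- interpolate_track(tibble::tibble(t = c(0, 1200), lon = 0:1, lat = 0:1),
                           max_gap_min = 10)
  expect_true(all(gap$gap[gap$t > 0 & gap$t < 1200]))
})

test_that("colony indicator follows the distance thresholds and steps scale with speed", {
  colony <- c(lon = -78.9636, lat = -8.5447)
  deg_per_km <- 1 / 111.1949
  tr <- tibble::tibble(
    t = c(0, 60, 120), minute = 0:2,
    lon = rep(colony[["lon"]], 3),
    lat = colony[["lat"]] + c(0.4, 2, 0.75) * deg_per_km
  )
  sc <- step_and_colony(tr, colony)
  expect_equal(sc$colony, c(1L, 0L, 0L)) # 0.4 km in; 2 km out; band -> 0
  # 10 m/s constant velocity gives 600 m steps on a planar track
  trp <- tibble::tibble(t = c(0, 60, 120), minute = 0:2,
                        x_km = c(0, 0.6, 1.2), y_km = 0)
  scp <- step_and_colony(trp, c(x_km = 0, y_km = 0))
  expect_equal(scp$step_m[2:3], c(600, 600))
  expect_true(is.na(scp$step_m[1]))
})

test_that("end-to-end features match ground truth on a gap-free simulated bird", {
  sc <- sim_scenario(seed = 21, deployment_hours = c(4, 4), gps_gap_prob = 0)
  st <- simulate_states(sc, 1)
  sb <- simulate_sensors(st, sc)
  mf <- minute_features(sb$accel, sb$depth, sb$gps, sc$colony,
                        wingbeat_stride_s = 10)
  truth <- st$state[mf$minute + 1]
  # colony stream equals the ground-truth colony indicator exactly
  expect_equal(mf$colony, as.integer(truth == "colony"))
  # dives only in foraging minutes
  expect_true(all(mf$dive_frac[truth != "foraging"] == 0))
  # per-state median wingbeat within one FFT bin of the scenario values
  med <- tapply(mf$wingbeat_hz, truth, median, na.rm = TRUE)
  pars <- sc$state_pars
  for (s in c("commuting", "foraging", "resting")) {
    if (!is.na(med[s])) {
      expect_lt(abs(med[s] - pars$wingbeat_hz[pars$state == s]), 1 / 30 + 1e-9)
    }
  }
  expect_true(all(mf$dba >= 0, na.rm = TRUE))
})
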