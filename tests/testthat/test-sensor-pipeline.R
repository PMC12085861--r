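test_that("wavelet transform round-trips losslessly without thresholding", {
  set.seed(101)
  for (n in c(64, 100, 1000, 1237)) {
    x <- rnorm(n) + sin(seq_len(n) / 7)
    expect_lt(max(abs(wavelet_denoise(x, threshold = "none") - x)), 1e-10)
    w <- dwt_periodic(x, levels = 4)
    expect_lt(max(abs(idwt_periodic(w) - x)), 1e-10)
  }
  expect_identical(wavelet_denoise(numeric(16)), numeric(16))
  expect_error(wavelet_denoise(1:4), "too short")
})

test_that("db2 filter variant also reconstructs exactly", {
  set.seed(102)
  x <- cumsum(rnorm(256))
  expect_lt(max(abs(wavelet_denoise(x, wavelet = "db2",
                                    threshold = "none") - x)), 1e-10)
})

test_that("SURE denoising reduces the RMSE of a noisy ramp", {
  set.seed(2024)
  n <- 1024
  clean <- seq(0, 5, length.out = n)
  noisy <- clean + rnorm(n, sd = 0.1)
  den <- wavelet_denoise(noisy)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))
})

test_that("EKF keeps a stationary platform still and covariances PSD", {
  set.seed(55)
  n <- 500; dt <- 0.02
  trace <- data.frame(
    t_s = (0:(n - 1)) * dt,
    ax = rnorm(n, 0, 0.02), ay = rnorm(n, 0, 0.02),
    az = 9.8 + rnorm(n, 0, 0.02),
    gx = rnorm(n, 0, 0.005), gy = rnorm(n, 0, 0.005),
    gz = rnorm(n, 0, 0.005),
    mx = cos(0.4) + rnorm(n, 0, 0.01),
    my = sin(0.4) + rnorm(n, 0, 0.01),
    mz = 0.4 + rnorm(n, 0, 0.01))
  pose <- ekf_fuse(trace)
  expect_lt(max(abs(pose$y)), 0.2)               # drift bounded
  expect_lt(max(abs(pose$x)), 0.2)
  expect_lt(max(abs(pose$heading - 0.4)), 0.05)
  expect_true(all(pose$P_mineig > -1e-10))       # symmetric PSD throughout
  expect_lt(max(abs(pose$P_final - t(pose$P_final))), 1e-12)
  # innovations zero-mean on matched data: |mean| < 2 SE per channel
  for (j in 1:4) {
    nu <- pose$innovations[, j]
    expect_lt(abs(mean(nu)), 2 * stats::sd(nu) / sqrt(length(nu)))
  }
})

test_that("EKF recovers a constant-velocity ascent within 5 percent", {
  # drift is a random draw per seed, so the bound is on the seed-set median
  tree <- palm_tree("WCT")
  errs <- sapply(1:5, function(s) {
    st <- synth_climber_trace(tree, climb_to = 1.4 + 12, climb_speed = 0.2,
                              sigma_accel = 0.05, n_slips = 0, n_scars = 0,
                              seed = s)
    m <- measure_tree(st$trace, frame_span = st$frame_span)
    abs(m$climb_m - 12) / 12
  })
  expect_lt(stats::median(errs), 0.05)
  st <- synth_climber_trace(tree, climb_to = 4, seed = 1)
  expect_error(ekf_fuse(st$trace, config = list(sigma_a = -1)), "positive")
})

test_that("ultrasonic diameter arithmetic and invalid-geometry flagging", {
  expect_equal(diameter_from_ultrasonic(0, 0, 0.6), 0.6,
               ignore_attr = TRUE)
  expect_equal(diameter_from_ultrasonic(0.20, 0.20, 0.60), 0.20,
               ignore_attr = TRUE)
  d <- diameter_from_ultrasonic(c(0.2, 0.5), c(0.2, 0.4), 0.6)
  expect_true(is.na(d[2]))
  expect_identical(attr(d, "invalid"), c(FALSE, TRUE))
  expect_error(diameter_from_ultrasonic(0.1, 0.1, 0), "positive")
})

test_that("rectification: identity on clean input, spike repair, PAVA height", {
  # clean monotone input passes through unchanged
  h <- seq(0, 5, by = 0.1)
  d <- rep(0.2, 51)
  r <- rectify_anomalies(height = h, diameter = d)
  expect_equal(r$height, h)
  expect_equal(r$diameter, d)
  expect_identical(r$n_flagged, 0L)

  # a +1 m spike in a smooth 0.2 m series is replaced
  d2 <- d; d2[25] <- d2[25] + 1
  r2 <- rectify_anomalies(diameter = d2)
  expect_lt(abs(r2$diameter[25] - 0.2), 1e-3)
  expect_true(25 %in% r2$flagged)

  # height dips are projected onto the isotonic cone (PAVA oracle)
  set.seed(12)
  for (i in 1:5) {
    y <- cumsum(runif(40, -0.2, 0.5))
    r3 <- rectify_anomalies(height = y)
    expect_equal(r3$height, pava_oracle(y), tolerance = 1e-10)
    expect_true(all(diff(r3$height) >= -1e-12))
  }
})

test_that("parameter extraction resamples diameter onto the height axis", {
  tree <- palm_tree("WCT")
  st <- synth_climber_trace(tree, climb_to = 11.4, sigma_accel = 0,
                            sigma_gyro = 0, sigma_mag = 0, sigma_us = 0,
                            n_slips = 0, n_scars = 0, seed = 1)
  m <- measure_tree(st$trace, frame_span = st$frame_span, denoise = FALSE)
  expect_lt(abs(m$total_height_m - 11.4) / 11.4, 0.05)
  expect_true(all(diff(m$profile$diameter_m) < 0))  # monotone taper
  # constant generator heading is recovered within the noise envelope
  expect_lt(max(abs(m$profile$heading_rad - st$heading)), 0.02)
  expect_equal(m$dbh_m, dbh(tree$taper), tolerance = 0.01)

  # zero-motion trace: zero climb, empty profile
  n <- 200
  still <- data.frame(t_s = (0:(n - 1)) * 0.02, ax = 0, ay = 0, az = 9.8,
                      gx = 0, gy = 0, gz = 0, mx = 1, my = 0, mz = 0.4,
                      us_left_m = 0.14, us_right_m = 0.14)
  m0 <- measure_tree(still, frame_span = 0.6, denoise = FALSE)
  expect_lt(m0$climb_m, 0.05)
  expect_identical(nrow(m0$profile), 0L)
  expect_error(extract_tree_parameters(list(t = 1:3, x = 1:3, y = 1:3,
                                            heading = 1:3), 1:5),
               "alignment")
})

test_that("sensor logs round-trip through CSV", {
  st <- synth_climber_trace(palm_tree("WCT"), climb_to = 3.5, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_sensor_trace(st$trace, f)
  rt <- read_sensor_trace(f)
  expect_equal(rt$az, st$trace$az, tolerance = 1e-12)
  g <- tempfile(fileext = ".csv")
  write_growth_series(simulate_growth(palm_tree("WCT"), years = 3), g)
  expect_error(read_sensor_trace(g), "not a sensor log")
  unlink(c(f, g))
})
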