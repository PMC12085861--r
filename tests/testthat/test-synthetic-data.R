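test_that("zero noise leaves growth observations identical", {
  g <- simulate_growth(palm_tree("WCT"), years = 10)
  obs <- synth_growth_observations(g, sigma_height = 0, sigma_dbh = 0,
                                  sigma_diameter = 0, seed = 5)
  expect_identical(obs$series, g$series)
  expect_identical(obs$profile, g$profile)
  expect_error(synth_growth_observations(g, sigma_height = -1), ">= 0")
})

test_that("seeded generators are exactly reproducible", {
  g <- simulate_growth(palm_tree("WCT"), years = 10)
  o1 <- synth_growth_observations(g, seed = 42)
  o2 <- synth_growth_observations(g, seed = 42)
  expect_identical(o1$series, o2$series)
  o3 <- synth_growth_observations(g, seed = 43)
  expect_false(identical(o1$series$height_m, o3$series$height_m))

  t1 <- synth_climber_trace(palm_tree("WCT"), climb_to = 4, seed = 7)
  t2 <- synth_climber_trace(palm_tree("WCT"), climb_to = 4, seed = 7)
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$truth, t2$truth)
})

test_that("generator does not disturb the global RNG stream", {
  set.seed(1); before <- .Random.seed
  invisible(synth_climber_trace(palm_tree("WCT"), climb_to = 3, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("injected height noise reappears in the error-variance metric", {
  # Monte-Carlo law: with sigma = 0.1 m i.i.d. noise on n heights, the
  # population error variance has mean sigma^2 (n-1)/n
  g <- simulate_growth(palm_tree("WCT"), years = 40, dt = 0.25)
  n <- nrow(g$series)
  vars <- sapply(1:200, function(s) {
    obs <- synth_growth_observations(g, sigma_height = 0.1, seed = s)
    compare_series(g$series$height_m, obs$series$height_m)$variance
  })
  expected <- 0.1^2 * (n - 1) / n
  se <- stats::sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - expected), 3 * se)
})

test_that("noiseless traces are inverted by the pipeline to integrator tolerance", {
  tree <- palm_tree("WCT")
  st <- synth_climber_trace(tree, climb_to = 6, sigma_accel = 0,
                            sigma_gyro = 0, sigma_mag = 0, sigma_us = 0,
                            n_slips = 0, n_scars = 0, seed = 1)
  m <- measure_tree(st$trace, frame_span = st$frame_span, denoise = FALSE)
  expect_lt(abs(m$climb_m - (6 - 1.4)) / (6 - 1.4), 0.01)
  expect_lt(abs(m$dbh_m - dbh(tree$taper)), 1e-3)
})

test_that("injected scar spikes are flagged by rectification", {
  tree <- palm_tree("WCT")
  st <- synth_climber_trace(tree, climb_to = 6, sigma_accel = 0,
                            sigma_gyro = 0, sigma_mag = 0, sigma_us = 0,
                            n_slips = 0, n_scars = 3, scar_magnitude = 0.05,
                            seed = 11)
  d <- diameter_from_ultrasonic(st$trace$us_left_m, st$trace$us_right_m,
                                st$frame_span)
  r <- rectify_anomalies(diameter = d)
  # every injected scar window contains a flagged sample
  for (si in st$scar_idx)
    expect_true(any(r$flagged %in% si:(si + 1L)))
  expect_gte(r$n_flagged, length(st$scar_idx))
})

test_that("generator validates its inputs", {
  expect_error(synth_climber_trace(palm_tree("WCT"), climb_to = 6,
                                   climb_speed = 0), "positive")
  expect_error(synth_climber_trace(palm_tree("WCT"), climb_to = 1.5),
               "too short")
})
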