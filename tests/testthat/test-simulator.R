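test_that("degenerate parameter set grows an exactly vertical trunk", {
  # beta_max = 0 and no wind: direction constant at theta0, no lateral shift,
  # height follows the constant-velocity law
  g <- simulate_growth(palm_tree("WCT"), years = 40, dt = 0.1)
  n <- nrow(g$series)
  expect_equal(g$series$height_m[n], 18.4, tolerance = 1e-9)
  expect_true(all(abs(g$profile$horizontal_shift_m) < 1e-12))
  expect_true(all(abs(g$profile$direction_rad - g$tree$theta0) < 1e-12))
  expect_true(all(abs(g$state$theta - g$tree$theta0) < 1e-12))
})

test_that("height series slope equals the apical velocity", {
  g <- simulate_growth(palm_tree("WCT"), years = 10, dt = 0.05)
  s <- g$series
  slopes <- diff(s$height_m) / diff(s$time_y)
  expect_true(all(abs(slopes - 0.46) < 1e-9))
})

test_that("DBH series equals twice the breast-height radius once reachable", {
  tree <- palm_tree("WCT")
  g <- simulate_growth(tree, years = 10, dt = 0.05)
  s <- g$series
  reach <- s$time_y * tree$a_v >= 1.4
  expect_true(all(is.na(s$dbh_m[!reach & s$time_y > 0]) |
                    !reach[s$time_y > 0][1]))
  expect_true(all(abs(s$dbh_m[reach] -
                        2 * radius_at_height(1.4, tree$taper)) < 1e-12))
  # diameter profile strictly decreasing with height
  expect_true(all(diff(g$profile$diameter_m) < 0))
})

test_that("simulation is deterministic: identical runs, bit-identical CSV", {
  g1 <- simulate_growth(palm_tree("WCT"), years = 8)
  g2 <- simulate_growth(palm_tree("WCT"), years = 8)
  expect_identical(g1$series, g2$series)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_growth_series(g1, f1); write_growth_series(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- read_growth_series(f1)
  expect_equal(rt$height_m, g1$series$height_m, tolerance = 1e-12)
  unlink(c(f1, f2))
})

test_that("comparison metrics match brute-force definitions", {
  set.seed(31)
  for (i in 1:10) {
    pred <- rnorm(10); obs <- rnorm(10)
    m <- compare_series(pred, obs)
    o <- metrics_oracle(pred, obs)
    expect_equal(m$variance, o$variance, tolerance = 1e-12)
    expect_equal(m$mae, o$mae, tolerance = 1e-12)
    expect_equal(m$rmse, o$rmse, tolerance = 1e-12)
    expect_equal(m$r2, o$r2, tolerance = 1e-12)
    expect_gte(m$rmse, m$mae)
    expect_lte(m$r2, 1)
    expect_gte(m$variance, 0)
  }
})

test_that("comparison metrics: identity, constant offset, unit scaling", {
  x <- c(1, 2, 3, 5, 8)
  m <- compare_series(x, x)
  expect_identical(c(m$variance, m$mae, m$rmse), c(0, 0, 0))
  expect_identical(m$r2, 1)

  m2 <- compare_series(x + 0.5, x)
  expect_equal(m2$mae, 0.5)
  expect_equal(m2$rmse, 0.5)
  expect_equal(m2$variance, 0)

  # metres reported as centimetres: variance scales by 100^2
  m3 <- compare_series(x + 0.5, x, scale = 100)
  expect_equal(m3$mae, 50)
  expect_error(compare_series(x, rep(1, 5)), "zero variance")
})

test_that("data-frame series are aligned by interpolation", {
  pred <- data.frame(t = seq(0, 10, 0.5), v = seq(0, 10, 0.5) * 2)
  obs <- data.frame(t = 1:9, v = (1:9) * 2 + 0.1)
  m <- compare_series(pred, obs)
  expect_equal(m$mae, 0.1, tolerance = 1e-12)
  expect_error(compare_series(pred, data.frame(t = 100:109, v = 1:10)),
               "alignment")
})

test_that("config files round-trip and unknown keys are rejected", {
  cfg <- tempfile(fileext = ".yml")
  writeLines(c("a_v: 0.3", "beta_max: 0", "x_base: 0.16", "x_dbh: 0.15"), cfg)
  tree <- palm_tree("custom", config = read_palm_config(cfg))
  expect_equal(tree$a_v, 0.3)
  expect_equal(dbh(tree$taper), 0.30, tolerance = 1e-12)

  writeLines(c("a_v: 0.3", "frobnicate: 1"), cfg)
  expect_error(read_palm_config(cfg), "unknown config key")
  expect_error(palm_tree(bogus_parameter = 1), "unknown parameter")
  unlink(cfg)
})

test_that("palm_tree methods expose coefficients and taper predictions", {
  tree <- palm_tree("WCT")
  co <- coef(tree)
  expect_equal(unname(co["a_v"]), 0.46)
  expect_equal(unname(co["beta_max"]), 0)
  expect_equal(predict(tree, height = 1.4), 0.32, tolerance = 1e-12)
  g <- simulate(tree, years = 5)
  expect_s3_class(g, "palm_growth")
  expect_equal(as.data.frame(g)$height_m[nrow(g$series)], 2.3,
               tolerance = 1e-9)
})
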