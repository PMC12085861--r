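test_that("environment-adjusted direction rotates f_p and stays unit", {
  ez <- c(0, 0, 1); ex <- c(1, 0, 0)
  fps <- (ez + 0.1 * ex) / sqrt(1.01)

  d0 <- env_adjusted_direction(ez, fps, theta = 0)
  expect_equal(d0$f_p_F, ez, tolerance = 1e-12)      # zero-angle identity

  set.seed(7)
  for (theta in runif(5, -pi, pi)) {
    d <- env_adjusted_direction(ez, fps, theta)
    expect_equal(sum(d$f_p_F^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(d$f_p_gamma * fps)), 1e-12)    # f_p_gamma _|_ f_p_star
    expect_lt(abs(sum(d$f_p_beta * d$f_p_gamma)), 1e-12)
  }

  expect_error(env_adjusted_direction(ez, ez, 0.3), "degenerate")
})

test_that("strict literal cross-product mode is exposed but degenerate", {
  ez <- c(0, 0, 1); fps <- c(0.1, 0, 1) / sqrt(1.01)
  d <- env_adjusted_direction(ez, fps, pi / 4, strict_literal = TRUE)
  expect_equal(sum(d$f_p_F^2), 1, tolerance = 1e-12)
  # the literal composition is perpendicular to both constituents
  expect_lt(abs(sum(d$f_p_F * ez)), 1e-12)
  expect_error(env_adjusted_direction(ez, fps, 0, strict_literal = TRUE),
               "vanished")
})

test_that("tropism strains: aligned target and zero beta_max give straight growth", {
  fr <- material_frame()
  s <- tropism_strains(fr$f3, fr, beta_max = 1.5)
  expect_identical(c(s$beta0, s$dbeta0_dr, s$gamma0), c(0, 0, 0))

  set.seed(11)
  for (i in 1:10) {
    s0 <- tropism_strains(runit(), fr, beta_max = 0)
    expect_identical(c(s0$beta0, s0$dbeta0_dr, s0$gamma0), c(0, 0, 0))
  }
})

test_that("tropism strains match the printed closed forms on axis targets", {
  fr <- material_frame()
  bm <- 2.0
  s <- tropism_strains(fr$f1, fr, beta_max = bm)
  expect_equal(s$beta0, bm / sqrt(2))
  expect_equal(s$dbeta0_dr, bm^2 / 2 * (1 - sqrt(2)))
  expect_equal(s$gamma0, 0)
  expect_error(tropism_strains(c(2, 0, 0), fr, 1), "unit")
})

test_that("projection system is exactly consistent at the delta-matched curvature scale", {
  # the closed-form strains satisfy the second-order projection relations
  # exactly when beta_max = 2/delta (curvature reaching the target in delta)
  fr <- material_frame()
  set.seed(5)
  for (delta in c(0.1, 0.05, 0.025)) {
    for (i in 1:50) {
      tgt <- runit()
      s <- tropism_strains(tgt, fr, beta_max = 2 / delta)
      res <- tropism_residuals(s, tgt, fr, delta)
      expect_lt(max(abs(res)), 1e-9 * delta^2 / 0.025^2 + 1e-12)
    }
  }
})

test_that("tangential projection residual is second order for near-axis targets", {
  # fixed beta_max, target at angular offset proportional to delta: the f3
  # projection residual must shrink at order >= 2
  fr <- material_frame()
  bm <- 1.0
  kappa <- 0.8
  deltas <- c(0.1, 0.05, 0.025)
  res3 <- sapply(deltas, function(delta) {
    phi <- kappa * delta
    tgt <- cos(phi) * fr$f3 + sin(phi) * fr$f1
    s <- tropism_strains(tgt, fr, beta_max = bm)
    abs(tropism_residuals(s, tgt, fr, delta)[3])
  })
  orders <- log2(res3[-length(res3)] / res3[-1])
  expect_true(all(orders >= 2 - 0.1))
})

test_that("differential-maturation curvature rate follows the sine law", {
  expect_equal(dms_curvature_rate(0.01, 0.01, 0.001, 0.61 * pi, 0.61 * pi), 0)
  # direct arithmetic oracle at the experimental parameter set
  p <- dms_curvature_rate(0.01, 0.01, 0.001, 0.61 * pi, 0)
  expect_equal(p, 2 * 0.01 / 0.01^2 * 0.001 * sin(0.61 * pi))
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, -pi, pi); b <- runif(1, -pi, pi)
    expect_equal(dms_curvature_rate(0.01, 0.01, 0.001, a, b),
                 -dms_curvature_rate(0.01, 0.01, 0.001, b, a))
  }
  expect_error(dms_curvature_rate(0.01, 0, 0.001, 1, 0), "positive")
})

test_that("apical step: unloaded straight rod is a fixed point", {
  st <- apical_state(seq(0, 2, by = 0.05), theta0 = 0.1)
  st2 <- apical_step(st, function(r) rep(5, length(r)), dt = 0.05)
  expect_equal(st2$q, st$q, tolerance = 1e-15)
  expect_equal(st2$theta, st$theta, tolerance = 1e-15)
  expect_equal(st2$bstar, st$bstar, tolerance = 1e-15)
  expect_equal(st2$s, st$s, tolerance = 1e-15)
})

test_that("apical step: constant lateral load gives the hand-integrated couple", {
  # dq/dr = -p_y cos(theta) with theta = 0 and q(k) = 0  =>  q = p_y (k - r)
  k <- 2; py <- 0.3
  st <- apical_state(seq(0, k, by = 0.01), theta0 = 0, p_y = py)
  st2 <- apical_step(st, function(r) rep(10, length(r)), dt = 0.05)
  expect_equal(st2$q, py * (k - st$r), tolerance = 1e-9)
  expect_equal(st2$q[length(st2$q)], 0)          # free tip
  expect_equal(st2$theta[1], 0)                  # clamped base
  expect_equal(unname(st2$s[1, ]), c(0, 0))      # clamped base position
})

test_that("apical step validates rigidity and extension seeds new material", {
  st <- apical_state(seq(0, 1, by = 0.1))
  expect_error(apical_step(st, function(r) rep(-1, length(r)), 0.05),
               "positive")
  st2 <- apical_extend(st, 1.5, dr = 0.1, bstar_new = 0.2)
  expect_equal(st2$r[length(st2$r)], 1.5)
  expect_true(all(st2$bstar[st2$r > 1 + 1e-9] == 0.2))
  expect_true(all(st2$bstar[st2$r <= 1] == 0))
})
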