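test_that("quadratic-plateau curve evaluates the two branches", {
  p <- quadplateau_params(0, 0.8, 1)
  expect_equal(p$b2, -0.4)
  expect_equal(quadplateau_predict(p, 0.5), 0.3)
  expect_equal(quadplateau_predict(p, 2), 0.4)
  expect_equal(quadplateau_predict(p, 0), 0)
  p2 <- quadplateau_params(-0.07, 1.3, 0.8)
  expect_equal(quadplateau_predict(p2, 0), -0.07)
  # smooth join: derivative vanishes at the breakpoint
  expect_equal(p2$b1 + 2 * p2$b2 * p2$cx, 0)
  # plateau identity b0 + b1*cx/2
  expect_equal(quadplateau_predict(p2, 10), -0.07 + 1.3 * 0.8 / 2)
  expect_error(quadplateau_params(0, 0.8, -1), "cx")
})

test_that("hockey-stick curve is continuous with an abrupt join", {
  p <- hockeystick_params(-0.1, 0.5, 1)
  expect_equal(hockeystick_predict(p, 0.5), 0.15)
  expect_equal(hockeystick_predict(p, c(1, 2, 4.5)), rep(0.4, 3))
  eps <- 1e-9
  expect_equal(hockeystick_predict(p, 1 - eps), hockeystick_predict(p, 1),
               tolerance = 1e-6)
})

test_that("self-start recipe brackets the truth and flags degeneracy", {
  d <- curve_data(quadplateau_params(0, 0.8, 1))
  st <- selfstart_quadplateau(d$x, d$y)
  expect_false(st$degenerate)
  expect_gt(st$cx, 0.5)
  expect_lt(st$cx, 2)

  flat <- selfstart_quadplateau(d$x, rep(2, length(d$x)))
  expect_true(flat$degenerate)

  # convex, never-saturating data: start clamps to the largest concentration
  conv <- selfstart_quadplateau(d$x, d$x^2)
  expect_equal(conv$cx, max(d$x))

  expect_error(selfstart_quadplateau(c(1, 2, 3), c(1, 2, 3)),
               "insufficient design")
})

test_that("noiseless data are recovered exactly by both models", {
  truth <- quadplateau_params(-0.05, 1.2, 0.7)
  d <- curve_data(truth)
  f <- fit_quadratic_plateau(d$x, d$y)
  expect_equal(f$params$b0, truth$b0, tolerance = 1e-6)
  expect_equal(f$params$b1, truth$b1, tolerance = 1e-6)
  expect_equal(f$params$cx, truth$cx, tolerance = 1e-6)
  expect_equal(f$plateau_elevation, -0.05 + 1.2 * 0.35, tolerance = 1e-6)
  expect_equal(f$tfl, derive_tfl(truth), tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)

  ht <- hockeystick_params(-0.1, 0.5, 1)
  dh <- curve_data(ht, predict_fun = hockeystick_predict)
  fh <- fit_hockey_stick(dh$x, dh$y)
  expect_equal(fh$params$b0, -0.1, tolerance = 1e-6)
  expect_equal(fh$params$b1, 0.5, tolerance = 1e-6)
  expect_equal(fh$params$cx, 1, tolerance = 1e-6)
  expect_equal(fh$tfl, 0.2, tolerance = 1e-6)
  expect_equal(fh$plateau_elevation, 0.4, tolerance = 1e-6)
})

test_that("fitted RSS never exceeds the truth's RSS on noisy data", {
  truth <- quadplateau_params(0, 0.8, 1)
  d <- noisy_curve_data(truth, sd = 0.03, seed = 17)
  f <- fit_quadratic_plateau(d$x, d$y)
  rss_truth <- sum((d$y - quadplateau_predict(truth, d$x))^2)
  expect_lte(f$rss, rss_truth)
})

test_that("breakpoints beyond the design hit the boundary and are flagged", {
  truth <- quadplateau_params(0, 0.1, 8)  # saturates past the gradient
  d <- curve_data(truth)
  f <- fit_quadratic_plateau(d$x, d$y)
  expect_equal(f$params$cx, 4.5, tolerance = 1e-6)
  expect_true(f$boundary)
})

test_that("TFL is the x-intercept on the rising branch", {
  expect_equal(derive_tfl(quadplateau_params(-0.1, 0.8, 1)),
               1 - sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(derive_tfl(quadplateau_params(0, 0.8, 1)), 0)
  expect_true(is.na(derive_tfl(quadplateau_params(0.05, 0.8, 1))))
  # whole curve below zero: no crossing, not estimable
  expect_true(is.na(derive_tfl(quadplateau_params(-10, 0.1, 1))))
  expect_equal(derive_tfl(hockeystick_params(-0.1, 0.5, 1)), 0.2)
  expect_equal(derive_tfl(hockeystick_params(0, 0.5, 1)), 0)
  expect_true(is.na(derive_tfl(hockeystick_params(-1, 0.5, 1))))
})

test_that("profiled-grid oracle agrees with the optimizer", {
  grid <- exp(seq(log(0.0125), log(4.5), length.out = 1000))
  set.seed(23)
  for (i in 1:10) {
    truth <- quadplateau_params(runif(1, -0.1, 0.05), runif(1, 0.5, 1.5),
                                runif(1, 0.4, 1.6))
    d <- noisy_curve_data(truth, sd = 0.03, seed = sample.int(1e6, 1))
    f <- fit_quadratic_plateau(d$x, d$y)
    o <- profile_grid_oracle(d$x, d$y, grid)
    expect_gte(o$rss, f$rss - 1e-9)
    expect_lt(abs(f$rss - o$rss) / o$rss, 1e-3)
  }
  # single-point grid at the true breakpoint nails noiseless truth
  truth <- quadplateau_params(-0.05, 1.2, 0.7)
  d <- curve_data(truth)
  o1 <- profile_grid_oracle(d$x, d$y, 0.7)
  expect_equal(o1$params$b0, -0.05, tolerance = 1e-9)
  expect_equal(o1$params$b1, 1.2, tolerance = 1e-9)
  expect_lt(o1$rss, 1e-15)
})

test_that("rescaling the response rescales elevations but not breakpoints", {
  truth <- quadplateau_params(-0.05, 1.2, 0.7)
  d <- noisy_curve_data(truth, sd = 0.02, seed = 5)
  f1 <- fit_quadratic_plateau(d$x, d$y)
  k <- 3.7
  f2 <- fit_quadratic_plateau(d$x, k * d$y)
  expect_equal(f2$params$b0, k * f1$params$b0, tolerance = 1e-5)
  expect_equal(f2$params$b1, k * f1$params$b1, tolerance = 1e-5)
  expect_equal(f2$plateau_elevation, k * f1$plateau_elevation,
               tolerance = 1e-5)
  expect_equal(f2$params$cx, f1$params$cx, tolerance = 1e-5)
  expect_equal(f2$tfl, f1$tfl, tolerance = 1e-5)
})

test_that("fits reject insufficient designs", {
  expect_error(fit_quadratic_plateau(c(1, 2, 3, 1, 2, 3), rep(1, 6)),
               "insufficient design")
  expect_error(fit_quadratic_plateau(c(1, 2, 3, 4), 1:4),
               "insufficient design")
})

test_that("every fit satisfies the smooth-join and plateau identities", {
  set.seed(31)
  for (i in 1:10) {
    truth <- quadplateau_params(runif(1, -0.1, 0.02), runif(1, 0.6, 1.4),
                                runif(1, 0.3, 2))
    d <- noisy_curve_data(truth, sd = 0.04, seed = sample.int(1e6, 1))
    f <- fit_quadratic_plateau(d$x, d$y)
    p <- f$params
    expect_equal(p$b1 + 2 * p$b2 * p$cx, 0, tolerance = 1e-10)
    expect_equal(f$plateau_elevation, p$b0 + p$b1 * p$cx / 2,
                 tolerance = 1e-10)
    expect_equal(f$plateau_elevation, quadplateau_predict(p, p$cx),
                 tolerance = 1e-10)
  }
})
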