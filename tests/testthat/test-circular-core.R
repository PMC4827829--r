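test_that("wrap_angle reduces modulo 2*pi onto [0, 2*pi)", {
  expect_equal(wrap_angle(0), 0)
  expect_equal(wrap_angle(2 * pi), 0)
  expect_equal(wrap_angle(-pi / 2), 3 * pi / 2)
  set.seed(42)
  th <- stats::runif(200, -50, 50)
  k <- sample(-5:5, 200, replace = TRUE)
  expect_equal(wrap_angle(th + 2 * pi * k), wrap_angle(th), tolerance = 1e-9)
  w <- wrap_angle(th)
  expect_true(all(w >= 0 & w < 2 * pi))
  expect_error(wrap_angle(Inf), "finite")
  expect_error(wrap_angle(NA_real_), "finite")
})

test_that("circular distance matches its closed form and metric properties", {
  expect_equal(circ_dist(0, 0), 0)
  expect_equal(circ_dist(pi, 0), pi)
  expect_equal(circ_dist(0.2, 6.2), 2 * pi - 6, tolerance = 1e-12)
  set.seed(7)
  a <- stats::runif(300, -20, 20)
  b <- stats::runif(300, -20, 20)
  d <- circ_dist(a, b)
  expect_equal(d, circ_dist(b, a))
  expect_true(all(d >= 0 & d <= pi + 1e-12))
  expect_equal(circ_dist(a + 2 * pi, b), d, tolerance = 1e-9)
  expect_equal(circ_dist(a, b - 4 * pi), d, tolerance = 1e-9)
  # zero iff coincident after wrapping
  expect_equal(circ_dist(a, a + 2 * pi * sample(-3:3, 300, TRUE)),
               rep(0, 300), tolerance = 1e-9)
  expect_true(all(circ_dist(a, a + 0.01) > 0))
})

test_that("A1 matches an integral-representation oracle and is monotone", {
  expect_equal(A1(0), 0)
  expect_equal(A1(2), ref_A1(2), tolerance = 1e-9)
  expect_equal(A1(2), 0.69777, tolerance = 1e-5)
  expect_gt(A1(20), 0.97)
  ks <- seq(0, 50, by = 0.1)
  vals <- A1(ks)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))
  expect_error(A1(-1), "non-negative")
})

test_that("concentration estimation inverts A1", {
  expect_equal(A1inv(0), 0)
  expect_equal(A1inv(A1(5)), 5, tolerance = 1e-6)
  ks <- seq(0.1, 50, by = 0.5)
  back <- vapply(A1(ks), A1inv, numeric(1))
  expect_equal(back, ks, tolerance = 1e-6)
  # a circadian-style sample with mean resultant length 0.74 has ML
  # concentration near 2.25-2.29 (the printed input is rounded to 2 dp)
  expect_equal(A1inv(0.74), 2.25, tolerance = 0.05)
  expect_error(A1inv(-0.1), "\\[0, 1\\)")
  expect_error(A1inv(1), "\\[0, 1\\)")
})

test_that("von Mises sampling concentrates as theory predicts", {
  x <- rvm(1000, 0, 1000, seed = 1)
  m <- atan2(mean(sin(x)), mean(cos(x)))
  expect_lt(abs(m), 0.05)
  y <- rvm(5000, pi / 2, 3, seed = 2)
  rbar <- sqrt(mean(cos(y))^2 + mean(sin(y))^2)
  expect_equal(rbar, A1(3), tolerance = 0.02)
  z <- rvm(1, 0, 0, seed = 3)
  expect_true(z >= 0 && z < 2 * pi)
  # high-concentration circular sd approaches 1/sqrt(kappa)
  w <- rvm(10000, 0, 100, seed = 4)
  cs <- sqrt(-2 * log(sqrt(mean(cos(w))^2 + mean(sin(w))^2)))
  expect_equal(cs, 1 / sqrt(100), tolerance = 0.1 * 1 / sqrt(100))
  expect_identical(rvm(50, 1, 2, seed = 9), rvm(50, 1, 2, seed = 9))
  expect_error(rvm(10, 0, -1), "non-negative")
})

test_that("circular summaries handle degenerate and simple samples", {
  s <- circ_summary(rep(1, 5))
  expect_equal(s$mean_direction, 1)
  expect_equal(s$mean_resultant_length, 1)
  expect_equal(s$circular_sd, 0)
  s2 <- circ_summary(c(0, pi))
  expect_lt(s2$mean_resultant_length, 1e-8)
  s3 <- circ_summary(c(0, pi / 2))
  expect_equal(s3$mean_direction, pi / 4)
  expect_equal(s3$mean_resultant_length, cos(pi / 4), tolerance = 1e-9)
  expect_error(circ_summary(numeric(0)), "empty")
})
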