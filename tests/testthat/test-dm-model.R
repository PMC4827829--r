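test_that("prediction follows the model equation", {
  p <- dm_params(0, 0, 0.5)
  expect_equal(dm_predict(pi / 2, p), 2 * atan(0.5), tolerance = 1e-12)
  # u = alpha maps to beta for any slope
  for (w in c(-1, -0.3, 0.2, 1))
    expect_equal(dm_predict(1.2, dm_params(1.2, 0.7, w)), 0.7,
                 tolerance = 1e-12)
  # identity map when omega = 1, alpha = beta = 0
  expect_equal(dm_predict(1.0, dm_params(0, 0, 1)), 1.0, tolerance = 1e-12)
  set.seed(3)
  u <- stats::runif(100, 0, 2 * pi)
  expect_equal(dm_predict(u, p), ref_predict(u, 0, 0, 0.5), tolerance = 1e-10)
  expect_error(dm_params(0, 0, 1.5), "omega")
})

test_that("prediction at the branch point takes the limiting value", {
  p <- dm_params(0.5, 1, 0.7)
  expect_equal(dm_predict(0.5 + pi, p), wrap_angle(1 + pi), tolerance = 1e-6)
  pneg <- dm_params(0.5, 1, -0.7)
  expect_equal(dm_predict(0.5 + pi, pneg), wrap_angle(1 - pi), tolerance = 1e-6)
  p0 <- dm_params(0.5, 1, 0)
  expect_equal(dm_predict(0.5 + pi, p0), 1, tolerance = 1e-12)
})

test_that("prediction is a bijection of the circle for nonzero slope", {
  p <- dm_params(0.8, -0.4, 0.35)
  u <- seq(0.8 - pi + 1e-6, 0.8 + pi - 1e-6, length.out = 2000)
  mu <- p$beta + 2 * atan(p$omega * tan((u - p$alpha) / 2))  # unwrapped
  expect_true(all(diff(mu) > 0))
  expect_equal(max(mu) - min(mu), 2 * pi, tolerance = 1e-2)
})

test_that("rho is the mean cosine of the angular errors", {
  p <- dm_params(0.3, 1.1, 0.6)
  set.seed(4)
  u <- stats::runif(20, 0, 2 * pi)
  x <- angle_pairs(u, dm_predict(u, p))
  expect_equal(dm_rho(x, p), 1, tolerance = 1e-12)
  x2 <- angle_pairs(u, wrap_angle(dm_predict(u, p) + pi))
  expect_equal(dm_rho(x2, p), -1, tolerance = 1e-12)
  u2 <- c(0.2, 1.4)
  x3 <- angle_pairs(u2, wrap_angle(dm_predict(u2, p) + c(0, pi / 2)))
  expect_equal(dm_rho(x3, p), 0.5, tolerance = 1e-12)
  set.seed(5)
  u3 <- stats::runif(50, 0, 2 * pi)
  v3 <- stats::runif(50, 0, 2 * pi)
  x4 <- angle_pairs(u3, v3)
  expect_equal(dm_rho(x4, p), ref_rho(u3, v3, c(0.3, 1.1, 0.6)),
               tolerance = 1e-12)
})

test_that("log-likelihood matches the von Mises form and its kappa profile", {
  p <- dm_params(0.3, 1.1, 0.6)
  set.seed(6)
  u <- stats::runif(10, 0, 2 * pi)
  perfect <- angle_pairs(u, dm_predict(u, p))
  expect_equal(dm_loglik(perfect, p, 0), 0)
  expect_equal(dm_loglik(perfect, p, 2), -10 * log(besselI(2, 0)) + 20,
               tolerance = 1e-9)
  noisy <- angle_pairs(u, wrap_angle(dm_predict(u, p) + rvm(10, 0, 4, seed = 8)))
  rho <- dm_rho(noisy, p)
  kh <- A1inv(rho)
  l0 <- dm_loglik(noisy, p, kh)
  expect_gte(l0, dm_loglik(noisy, p, kh + 0.5))
  expect_gte(l0, dm_loglik(noisy, p, max(0, kh - 0.5)))
  expect_error(dm_loglik(noisy, p, -1), "non-negative")
})

test_that("grid initialization recovers lattice-exact parameters", {
  # truth on the default lattice: alpha, beta multiples of pi/60, omega of 0.05
  truth <- c(30 * pi / 60 - pi, 30 * pi / 60 - pi, 0.5)  # (-pi/2, -pi/2, 0.5)
  x <- exact_curve_data(25, truth, u_seed = 10)
  g <- dm_grid_init(x)
  expect_equal(g$alpha, truth[1], tolerance = 1e-9)
  expect_equal(g$beta, truth[2], tolerance = 1e-9)
  expect_equal(g$omega, truth[3], tolerance = 1e-9)
  # off-lattice truth lands within one step
  truth2 <- c(1.5, 1.5, 0.48)
  x2 <- exact_curve_data(40, truth2, u_seed = 11)
  g2 <- dm_grid_init(x2)
  expect_lt(abs(g2$alpha - 1.5), pi / 60 + 1e-9)
  expect_lt(abs(g2$beta - 1.5), pi / 60 + 1e-9)
  expect_lt(abs(g2$omega - 0.48), 0.05 + 1e-9)
  expect_error(dm_grid_init(x, alpha_step = -1), "positive")
})

test_that("grid initialization agrees with a brute-force lattice scan", {
  set.seed(12)
  u <- stats::runif(12, 0, 2 * pi)
  v <- stats::runif(12, 0, 2 * pi)
  x <- angle_pairs(u, v)
  astep <- pi / 6
  wstep <- 0.25
  g <- dm_grid_init(x, alpha_step = astep, omega_step = wstep)
  al <- seq(-pi, pi - 1e-9, by = astep)
  wl <- setdiff(seq(-1, 1, by = wstep), 0)
  best <- -2; bp <- NULL
  for (a in al) for (b in al) for (w in wl) {
    r <- ref_rho(u, v, c(a, b, w))
    if (r > best) { best <- r; bp <- c(a, b, w) }
  }
  expect_equal(c(g$alpha, g$beta, g$omega), bp, tolerance = 1e-9)
})

test_that("maximum-likelihood fit recovers noise-free parameters", {
  truth <- c(1.5, 1.5, 0.5)
  set.seed(13)
  u <- rvm(50, pi / 2, 3)
  x <- angle_pairs(u, ref_predict(u, 1.5, 1.5, 0.5))
  f <- dm_fit(x)
  expect_lt(abs(f$params$alpha - 1.5), 1e-3)
  expect_lt(abs(f$params$beta - 1.5), 1e-3)
  expect_lt(abs(f$params$omega - 0.5), 1e-3)
  expect_gte(f$rho_hat, 1 - 1e-6)
  expect_true(all(f$residuals >= 0 & f$residuals <= pi))
  expect_equal(length(f$fitted), f$n)
  # rho at the estimates reproduces the definition, and kappa inverts it
  expect_equal(f$rho_hat, mean(cos(wrap_angle(x$v - f$fitted + pi) - pi)),
               tolerance = 1e-9)
  expect_error(dm_fit(angle_pairs(u[1:3], u[1:3])), "at least 4")
})

test_that("compiled fitter agrees with a stats::optim reference", {
  truth <- c(0.9, -0.7, 0.6)
  set.seed(14)
  for (rep in 1:5) {
    u <- rvm(30, pi / 2, 3)
    v <- wrap_angle(ref_predict(u, truth[1], truth[2], truth[3]) +
                      rvm(30, 0, 10))
    x <- angle_pairs(u, v)
    g <- dm_grid_init(x)
    f <- dm_fit(x, init = g)
    o <- ref_fit(u, v, c(g$alpha, g$beta, g$omega))
    expect_equal(f$rho_hat, o$rho, tolerance = 1e-6)
  }
})

test_that("fit is equivariant under rotation of the response", {
  set.seed(15)
  u <- rvm(40, pi / 2, 3)
  v <- wrap_angle(ref_predict(u, 1.5, 1.5, 0.5) + rvm(40, 0, 15))
  f1 <- dm_fit(angle_pairs(u, v))
  shift <- 0.8
  f2 <- dm_fit(angle_pairs(u, wrap_angle(v + shift)))
  expect_equal(f2$params$omega, f1$params$omega, tolerance = 1e-4)
  expect_lt(circ_dist(f2$params$beta, f1$params$beta + shift), 1e-4)
  expect_equal(f2$rho_hat, f1$rho_hat, tolerance = 1e-6)
})

test_that("optimization never loses to its own grid start", {
  set.seed(16)
  for (rep in 1:4) {
    u <- rvm(25, pi / 2, 3)
    v <- wrap_angle(ref_predict(u, 1.0, 0.5, 0.4) + rvm(25, 0, 5))
    x <- angle_pairs(u, v)
    g <- dm_grid_init(x)
    f <- dm_fit(x, init = g)
    expect_gte(f$rho_hat, dm_rho(x, g) - 1e-12)
  }
})
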