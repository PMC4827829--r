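# Independent reference implementations used as oracles.  These stay in
# plain R and deliberately share no code with the package internals: the
# model prediction is written out from the model equation, the fit goes
# through stats::optim on an R objective, and the deletion loop is a
# direct transcription of the statistic's definition.

ref_wrap <- function(x) x - 2 * pi * floor(x / (2 * pi))

ref_dist <- function(phi, theta) {
  p <- ref_wrap(phi); t <- ref_wrap(theta)
  pi - abs(pi - abs(p - t))
}

ref_predict <- function(u, alpha, beta, omega) {
  w <- ref_wrap(u - alpha)
  w <- ifelse(w > pi, w - 2 * pi, w)
  ref_wrap(beta + 2 * atan(omega * tan(w / 2)))
}

ref_rho <- function(u, v, p) {
  mean(cos(v - ref_predict(u, p[1], p[2], p[3])))
}

# maximum-likelihood fit through stats::optim (Nelder-Mead on an R
# objective with the slope held in [-1, 1] by penalty), grid-started
ref_fit <- function(u, v, init) {
  obj <- function(p) {
    w <- p[3]; pen <- 0
    if (abs(w) > 1) { pen <- abs(w) - 1; w <- sign(w) }
    -ref_rho(u, v, c(p[1], p[2], w)) + pen
  }
  o <- stats::optim(init, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  list(par = c(o$par[1:2], max(-1, min(1, o$par[3]))), rho = -o$value)
}

# A1 through the integral representation of the Bessel functions --
# independent of besselI
ref_A1 <- function(kappa) {
  I <- function(nu) stats::integrate(function(t) exp(kappa * (cos(t) - 1)) * cos(nu * t),
                                     0, pi, rel.tol = 1e-12)$value
  I(1) / I(0)
}

# brute-force fixed-parameter deletion loop for DMCEs (refit = FALSE)
ref_dmces_norefit <- function(u, v, params) {
  s <- sin(ref_dist(v, ref_predict(u, params[1], params[2], params[3])) / 2)
  n <- length(s)
  m <- mean(s)
  per <- vapply(seq_len(n), function(j) abs(m - mean(s[-j])), numeric(1))
  list(per = per, dmces = max(per), argmax = which.max(per))
}

# small helper: exact-curve dataset for a given parameter triple
exact_curve_data <- function(n, params, u_seed = 1) {
  set.seed(u_seed)
  u <- stats::runif(n, 0, 2 * pi)
  angle_pairs(u, ref_predict(u, params[1], params[2], params[3]))
}
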