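#' Downs-Mardia model parameters
#'
#' Bundles the three functionally independent parameters of the
#' circular-circular regression model
#' \deqn{\tan\frac{v - \beta}{2} = \omega \tan\frac{u - \alpha}{2},}
#' an angular location for each variable and a slope \eqn{\omega} confined
#' to \eqn{[-1, 1]}.  Locations are stored on the branch \eqn{(-\pi, \pi]}.
#'
#' @param alpha,beta Angular locations in radians.
#' @param omega Slope in \eqn{[-1, 1]}.
#' @return An object of class \code{dm_params}.
#' @examples
#' dm_params(1.5, 1.5, 0.5)
#' @export
dm_params <- function(alpha, beta, omega) {
  if (!all(is.finite(c(alpha, beta, omega))))
    stop("parameters must be finite", call. = FALSE)
  if (abs(omega) > 1)
    stop("omega must lie in [-1, 1]", call. = FALSE)
  structure(list(alpha = wrap_diff(alpha), beta = wrap_diff(beta),
                 omega = omega),
            class = "dm_params")
}

#' @export
print.dm_params <- function(x, ...) {
  cat(sprintf("DM parameters: alpha = %.4f, beta = %.4f, omega = %.4f\n",
              x$alpha, x$beta, x$omega))
  invisible(x)
}

#' Paired circular observations
#'
#' A sample of paired angles \eqn{(u_j, v_j)}: \code{u} is the independent
#' and \code{v} the dependent circular variable, both wrapped to
#' \eqn{[0, 2\pi)}.
#'
#' @param u,v Numeric vectors of equal length (radians).
#' @param labels Optional row labels, kept for reporting.
#' @return A data frame of class \code{angle_pairs} with columns \code{u}
#'   and \code{v}.
#' @examples
#' angle_pairs(c(0.1, 1, 2), c(0.2, 1.1, 2.3))
#' @export
angle_pairs <- function(u, v, labels = NULL) {
  if (length(u) != length(v)) stop("u and v must have equal length", call. = FALSE)
  if (length(u) < 1) stop("at least one pair is required", call. = FALSE)
  d <- data.frame(u = wrap_angle(u), v = wrap_angle(v))
  if (!is.null(labels)) rownames(d) <- labels
  class(d) <- c("angle_pairs", "data.frame")
  d
}

#' Predicted mean direction of the dependent angle
#'
#' The unique solution of the model equation,
#' \eqn{\mu(u) = \beta + 2 \arctan\{\omega \tan\frac{u - \alpha}{2}\}},
#' a one-to-one map of the circle whenever \eqn{\omega \ne 0}.  At the
#' branch point \eqn{u - \alpha = \pi} the limiting value
#' \eqn{\beta + \pi\,\mathrm{sign}(\omega)} is returned
#' (\eqn{\beta} itself when \eqn{\omega = 0}).
#'
#' @param u Numeric vector of angles in radians.
#' @param params A \code{\link{dm_params}} object.
#' @return Predicted angles, wrapped to \eqn{[0, 2\pi)}.
#' @examples
#' dm_predict(pi / 2, dm_params(0, 0, 0.5))  # 2 * atan(0.5)
#' @export
dm_predict <- function(u, params) {
  stopifnot(inherits(params, "dm_params"))
  u <- wrap_angle(u)
  dm_predict_cpp(u, params$alpha, params$beta, params$omega)
}

#' Precision estimate rho
#'
#' The mean cosine of the angular errors,
#' \eqn{\hat\rho(\alpha, \beta, \omega) = \frac{1}{n}\sum_j
#' \cos(v_j - \mu(u_j))}, the quantity the ML fit maximises.  Equals 1
#' exactly when every observation sits on the fitted curve and \eqn{-1}
#' when every observation is antipodal to it.
#'
#' @param data An \code{\link{angle_pairs}} sample.
#' @param params A \code{\link{dm_params}} object.
#' @return A number in \eqn{[-1, 1]}.
#' @export
dm_rho <- function(data, params) {
  stopifnot(inherits(data, "angle_pairs"), inherits(params, "dm_params"))
  dm_rho_cpp(data$u, data$v, params$alpha, params$beta, params$omega)
}

#' Log-likelihood of the fitted model
#'
#' Under von Mises errors \eqn{VM(0, \kappa)} the log-likelihood is
#' \deqn{\ell = -n \log I_0(\kappa) + \kappa \sum_j \cos(v_j - \mu(u_j)),}
#' up to an additive constant (dropped here).  For fixed
#' \eqn{(\alpha, \beta, \omega)} the profile over \eqn{\kappa} is maximised
#' at \eqn{\hat\kappa = A_1^{-1}(\hat\rho)}.
#'
#' @inheritParams dm_rho
#' @param kappa Non-negative concentration of the error distribution.
#' @return The log-likelihood value (constant dropped).
#' @export
dm_loglik <- function(data, params, kappa) {
  if (!is.finite(kappa) || kappa < 0)
    stop("kappa must be non-negative and finite", call. = FALSE)
  n <- nrow(data)
  # scaled Bessel: log I0(k) = log besselI(k, 0, TRUE) + k
  -n * (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa) +
    kappa * n * dm_rho(data, params)
}

#' Grid-search initialization of the model parameters
#'
#' Evaluates \eqn{\hat\rho} exhaustively on the lattice
#' \eqn{\alpha \in [-\pi, \pi)}, \eqn{\beta \in [-\pi, \pi)} (both stepped
#' by \code{alpha_step}) and \eqn{\omega \in [-1, 1]} stepped by
#' \code{omega_step} with \eqn{\omega = 0} excluded (the constant model is
#' degenerate), and returns the maximising triple.  Ties go to the
#' lexicographically smallest \eqn{(\alpha, \beta, \omega)}.  Default
#' steps are 3 degrees for the locations and 0.05 for the slope.
#'
#' @param data An \code{\link{angle_pairs}} sample.
#' @param alpha_step Lattice step for \eqn{\alpha} and \eqn{\beta}, radians.
#' @param omega_step Lattice step for \eqn{\omega}.
#' @return A \code{\link{dm_params}} object at the lattice maximiser.
#' @export
dm_grid_init <- function(data, alpha_step = pi / 60, omega_step = 0.05) {
  stopifnot(inherits(data, "angle_pairs"))
  if (alpha_step <= 0 || omega_step <= 0)
    stop("lattice steps must be positive", call. = FALSE)
  if (alpha_step > 2 * pi || omega_step > 2)
    stop("degenerate lattice: step larger than the search range", call. = FALSE)
  g <- dm_grid_cpp(data$u, data$v, alpha_step, omega_step)
  dm_params(g$alpha, g$beta, g$omega)
}

#' Maximum-likelihood fit of the Downs-Mardia model
#'
#' Maximises \eqn{\hat\rho} (equivalently the \eqn{\kappa}-profiled
#' log-likelihood) over \eqn{(\alpha, \beta, \omega)} with
#' \eqn{|\omega| \le 1}, by a bounded Nelder-Mead simplex started from
#' \code{init} or, when absent, from \code{\link{dm_grid_init}}.  The
#' error concentration is then estimated as
#' \eqn{\hat\kappa = A_1^{-1}(\hat\rho)}.
#'
#' @param data An \code{\link{angle_pairs}} sample with \eqn{n \ge 4}.
#' @param init Optional \code{\link{dm_params}} starting point.
#' @param control List of optimizer settings: \code{ftol}, \code{ptol},
#'   \code{maxit}, \code{restarts}, \code{step0} (initial simplex scale),
#'   and the grid steps \code{alpha_step}, \code{omega_step}.
#' @return An object of class \code{dm_fit}: the estimates (as
#'   \code{dm_params}), \code{rho_hat}, \code{kappa_hat}, fitted values,
#'   circular residuals \eqn{d_j \in [0, \pi]}, the log-likelihood at the
#'   optimum, and \code{n}.
#' @examples
#' set.seed(1)
#' u <- rvm(40, pi / 2, 3)
#' v <- dm_predict(u, dm_params(1.5, 1.5, 0.5))
#' fit <- dm_fit(angle_pairs(u, v))
#' fit$params
#' @export
dm_fit <- function(data, init = NULL, control = list()) {
  stopifnot(inherits(data, "angle_pairs"))
  n <- nrow(data)
  if (n < 4)
    stop("at least 4 pairs are needed to fit three parameters", call. = FALSE)
  ctl <- utils::modifyList(list(ftol = 1e-12, ptol = 1e-8, maxit = 1000,
                                restarts = 1, step0 = 0.2,
                                alpha_step = pi / 60, omega_step = 0.05),
                           control)
  if (is.null(init))
    init <- dm_grid_init(data, ctl$alpha_step, ctl$omega_step)
  stopifnot(inherits(init, "dm_params"))
  opt <- dm_fit_cpp(data$u, data$v,
                    c(init$alpha, init$beta, init$omega),
                    ftol = ctl$ftol, ptol = ctl$ptol, maxit = ctl$maxit,
                    restarts = ctl$restarts, step0 = ctl$step0)
  params <- dm_params(opt$alpha, opt$beta, opt$omega)
  rho <- opt$rho
  if (rho <= 0)
    stop("fit failed: precision estimate rho is non-positive at the optimum",
         call. = FALSE)
  # a numerically perfect fit has unbounded ML concentration; cap the mean
  # resultant length just below 1 so kappa_hat stays finite
  kappa <- A1inv(min(rho, 1 - 1e-9))
  fitted <- dm_predict(data$u, params)
  resid <- circ_dist(data$v, fitted)
  structure(list(params = params, rho_hat = rho, kappa_hat = kappa,
                 fitted = fitted, residuals = resid,
                 loglik = dm_loglik(data, params, kappa),
                 n = n, data = data, init = init),
            class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, digits = 4, ...) {
  cat("Downs-Mardia circular regression fit\n")
  cat(sprintf("  n = %d observations\n", x$n))
  cat(sprintf("  alpha = %.*f rad (%.2f deg)\n", digits, x$params$alpha,
              x$params$alpha * 180 / pi))
  cat(sprintf("  beta  = %.*f rad (%.2f deg)\n", digits, x$params$beta,
              x$params$beta * 180 / pi))
  cat(sprintf("  omega = %.*f\n", digits, x$params$omega))
  cat(sprintf("  rho = %.*f, kappa = %.*f, loglik = %.*f\n",
              digits, x$rho_hat, digits, x$kappa_hat, digits, x$loglik))
  invisible(x)
}
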