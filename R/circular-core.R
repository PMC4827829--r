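#' Wrap an angle onto the circle
#'
#' Reduces an angle (radians) modulo \eqn{2\pi} to the canonical range
#' \eqn{[0, 2\pi)}.  All internal computation in the package happens in
#' radians on this branch; degrees appear only at the I/O boundary.
#'
#' @param theta Numeric vector of angles in radians.  Must be finite.
#' @return Numeric vector of the same length with values in \eqn{[0, 2\pi)}.
#' @examples
#' wrap_angle(c(0, 2 * pi, -pi / 2))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("angles must be finite numeric values", call. = FALSE)
  theta %% (2 * pi)
}

# wrap a difference to (-pi, pi] (principal branch for tan(diff / 2))
wrap_diff <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Circular distance between two angles
#'
#' The length of the shorter arc between two points on the circle,
#' \eqn{d_\circ(\phi, \theta) = \pi - |\pi - |\phi - \theta||}, taking
#' values in \eqn{[0, \pi]}.  This is the distance used to define the
#' circular residuals of the regression model.
#'
#' @param phi,theta Numeric vectors of angles in radians (recycled).
#' @return Numeric vector of distances in \eqn{[0, \pi]}.
#' @examples
#' circ_dist(0, 0)
#' circ_dist(pi, 0)
#' circ_dist(0.2, 6.2)  # 2*pi - 6, about 0.28319
#' @export
circ_dist <- function(phi, theta) {
  phi <- wrap_angle(phi)
  theta <- wrap_angle(theta)
  pi - abs(pi - abs(phi - theta))
}

#' Draw from a von Mises distribution
#'
#' Samples the von Mises distribution \eqn{VM(\mu, \kappa)} by the
#' Best-Fisher wrapped-Cauchy rejection algorithm.  \code{kappa = 0} gives
#' the circular uniform distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter, \eqn{\kappa \ge 0}.
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return Numeric vector of \code{n} angles in \eqn{[0, 2\pi)}.
#' @examples
#' x <- rvm(100, mu = pi / 2, kappa = 3, seed = 7)
#' circ_summary(x)$mean_direction
#' @export
rvm <- function(n, mu = 0, kappa = 1, seed = NULL) {
  if (length(n) != 1L || n < 1) stop("n must be a positive integer", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0)
    stop("kappa must be a non-negative finite number", call. = FALSE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  # Best & Fisher (1979) envelope
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' First Bessel-function ratio A1
#'
#' \eqn{A_1(\kappa) = I_1(\kappa) / I_0(\kappa)}, the mean resultant length
#' of a von Mises distribution with concentration \eqn{\kappa}.  Strictly
#' increasing, 0 at \eqn{\kappa = 0} and approaching 1 as
#' \eqn{\kappa \to \infty}.  Evaluated with exponentially scaled Bessel
#' functions so it is overflow-safe for large \eqn{\kappa}.
#'
#' @param kappa Non-negative numeric vector.
#' @return Values of \eqn{A_1(\kappa)} in \eqn{[0, 1)}.
#' @examples
#' A1(c(0, 2, 20))
#' @export
A1 <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("kappa must be non-negative and finite", call. = FALSE)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Maximum-likelihood concentration from a mean resultant length
#'
#' Inverts \eqn{A_1} numerically: returns the \eqn{\kappa} solving
#' \eqn{A_1(\kappa) = \bar R}.  This is the ML estimator of the von Mises
#' concentration given the mean cosine of the errors (the precision
#' estimate of the regression model).
#'
#' @param rbar Mean resultant length, \eqn{0 \le \bar R < 1}.  A negative
#'   value is an error: a negative mean cosine means the model fits worse
#'   than an orthogonal predictor and must be handled by the caller.
#' @return Non-negative concentration \eqn{\hat\kappa}; 0 when
#'   \code{rbar = 0}.
#' @examples
#' A1inv(0.74)          # about 2.29
#' A1inv(A1(5))         # recovers 5
#' @export
A1inv <- function(rbar) {
  if (length(rbar) != 1L || !is.finite(rbar))
    stop("rbar must be a single finite number", call. = FALSE)
  if (rbar < 0 || rbar >= 1)
    stop("rbar must lie in [0, 1); negative precision indicates a failed fit",
         call. = FALSE)
  if (rbar == 0) return(0)
  if (rbar > A1(708)) return(1 / (2 * (1 - rbar)))  # asymptotic tail
  stats::uniroot(function(k) A1(k) - rbar, c(0, 708),
                 tol = 1e-10)$root
}

#' Circular descriptive statistics
#'
#' Mean direction, mean resultant length, circular standard deviation
#' \eqn{\sqrt{-2 \log \bar R}}, circular median (the angle among the data
#' points and pairwise circular midpoints minimising the mean circular
#' distance to the sample, ties going to the smallest wrapped value), and
#' the ML concentration \code{A1inv(rbar)}.
#'
#' @param theta Numeric vector of angles in radians, \eqn{n \ge 1}.
#' @return A list with components \code{mean_direction},
#'   \code{mean_resultant_length}, \code{circular_sd},
#'   \code{median_direction} and \code{concentration}.  When
#'   \eqn{\bar R = 0} the sd and concentration degenerate (\code{Inf} and
#'   0) and the mean direction is \code{NA}.
#' @examples
#' circ_summary(c(0, pi / 2))
#' @export
circ_summary <- function(theta) {
  if (length(theta) == 0) stop("empty sample", call. = FALSE)
  theta <- wrap_angle(theta)
  n <- length(theta)
  C <- mean(cos(theta))
  S <- mean(sin(theta))
  rbar <- sqrt(C^2 + S^2)
  mean_dir <- if (rbar > 0) wrap_angle(atan2(S, C)) else NA_real_
  circ_sd <- if (rbar > 0) sqrt(-2 * log(rbar)) else Inf
  # candidate medians: data points plus both circular midpoints of each
  # circularly adjacent pair (the objective is piecewise linear with breaks
  # only at data points and their antipodes, so the minimum lies there)
  srt <- sort(theta)
  cand <- theta
  if (n > 1) {
    nxt <- c(srt[-1], srt[1] + 2 * pi)
    mids <- wrap_angle((srt + nxt) / 2)
    cand <- c(cand, mids, wrap_angle(mids + pi))
  }
  cand <- sort(unique(cand))
  obj <- vapply(cand, function(m) mean(circ_dist(theta, m)), numeric(1))
  med <- cand[which(obj <= min(obj) + 1e-12)][1]
  list(mean_direction = mean_dir,
       mean_resultant_length = rbar,
       circular_sd = circ_sd,
       median_direction = med,
       concentration = if (rbar < 1) A1inv(rbar) else Inf)
}
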