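#' Simulation scheme for the DMCEs calibration study
#'
#' Describes the data-generating process used to calibrate cut-off points
#' and study detection power: the independent angle is drawn from
#' \eqn{VM(\pi/2, 3)}, the response is the model prediction at
#' \eqn{(\alpha, \beta, \omega) = (1.5, 1.5, 0.5)} plus a von Mises error
#' \eqn{VM(0, \kappa)}, and each experiment is replicated (2000 times by
#' default).
#'
#' @param n Sample size per replicate, \eqn{n \ge 5}.
#' @param error_kappa Concentration \eqn{\kappa} of the von Mises error.
#' @param params True model parameters (a \code{\link{dm_params}}).
#' @param u_mu,u_kappa Mean direction and concentration of the
#'   distribution of the independent angle.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Base seed; every replicate seed is derived from it, so a
#'   scheme reproduces exactly.
#' @return An object of class \code{dm_scheme}.
#' @examples
#' dm_scheme(n = 30, error_kappa = 10, reps = 500, seed = 1)
#' @export
dm_scheme <- function(n, error_kappa, params = dm_params(1.5, 1.5, 0.5),
                      u_mu = pi / 2, u_kappa = 3, reps = 2000, seed = 1) {
  if (n < 5) stop("scheme requires n >= 5", call. = FALSE)
  if (reps < 1) stop("reps must be at least 1", call. = FALSE)
  if (!is.finite(error_kappa) || error_kappa < 0)
    stop("error_kappa must be non-negative", call. = FALSE)
  stopifnot(inherits(params, "dm_params"))
  structure(list(n = n, error_kappa = error_kappa, params = params,
                 u_mu = u_mu, u_kappa = u_kappa, reps = reps,
                 seed = as.integer(seed)),
            class = "dm_scheme")
}

#' Simulate one clean dataset under a scheme
#'
#' Draws \eqn{u_j} from the scheme's von Mises law, errors
#' \eqn{\varepsilon_j} from \eqn{VM(0, \kappa)}, and sets
#' \eqn{v_j = \mu(u_j) + \varepsilon_j} wrapped to \eqn{[0, 2\pi)}.
#'
#' @param scheme A \code{\link{dm_scheme}}.
#' @param rep Replicate index (determines the derived seed together with
#'   the scheme's base seed).
#' @return An \code{\link{angle_pairs}} sample of size \code{scheme$n}.
#' @examples
#' x <- dm_simulate(dm_scheme(n = 30, error_kappa = 10, seed = 1), rep = 1)
#' nrow(x)
#' @export
dm_simulate <- function(scheme, rep = 1L) {
  stopifnot(inherits(scheme, "dm_scheme"))
  s <- replicate_seed(scheme, rep, stream = 0L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(s)
  u <- rvm(scheme$n, scheme$u_mu, scheme$u_kappa)
  eps <- rvm(scheme$n, 0, scheme$error_kappa)
  v <- wrap_angle(dm_predict(u, scheme$params) + eps)
  angle_pairs(u, v)
}

replicate_seed <- function(scheme, rep, stream = 0L) {
  m <- 2147483629
  h <- (as.double(scheme$seed) %% m) * 100003 +
    scheme$n * 131 + round(scheme$error_kappa * 1000) * 17 +
    as.double(stream) * 1299709 + as.double(rep) * 7919
  as.integer(h %% m) + 1L
}

#' Plant a contaminated observation
#'
#' Shifts the response of observation \code{d} by \eqn{\lambda \pi}
#' (modulo \eqn{2\pi}): \eqn{v_d^* = v_d + \lambda\pi}.  \eqn{\lambda = 0}
#' leaves the data unchanged; \eqn{\lambda = 1} moves the observation to
#' the anti-mode of its original position, the largest possible circular
#' perturbation.
#'
#' @param data An \code{\link{angle_pairs}} sample.
#' @param d Index of the observation to contaminate (1-based).
#' @param lambda Degree of contamination in \eqn{[0, 1]}.
#' @return A copy of \code{data} with \eqn{v_d} replaced.
#' @examples
#' x <- angle_pairs(c(1, 2, 3), c(1, 2, 3))
#' contaminate(x, d = 2, lambda = 1)$v
#' @export
contaminate <- function(data, d, lambda) {
  stopifnot(inherits(data, "angle_pairs"))
  if (length(d) != 1L || d < 1 || d > nrow(data) || d != round(d))
    stop("contamination index out of range", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  data$v[d] <- wrap_angle(data$v[d] + lambda * pi)
  data
}

#' Monte-Carlo cut-off points for the DMCEs statistic
#'
#' For every combination of sample size and error concentration, simulates
#' \code{scheme$reps} clean datasets, fits the model and computes the
#' row-deletion statistic per replicate, and returns the empirical upper
#' percentiles (linear-interpolated order statistics) at the requested
#' levels.  These percentiles are the cut-off points used by
#' \code{\link{dmces_detect}}.
#'
#' @param scheme A \code{\link{dm_scheme}} supplying the data-generating
#'   process, replicate count and base seed.
#' @param levels Upper-tail probabilities, each in (0, 1); default the
#'   10\%, 5\% and 1\% levels.
#' @param refit Logical: refit the model on each row deletion (see
#'   \code{\link{dmces}}).
#' @param n,kappa Optional vectors of sample sizes and error
#'   concentrations overriding the scheme's single values; the full grid
#'   is simulated.  Per-cell seeds derive from (seed, n, kappa), so a
#'   cell's cut-offs do not depend on which other cells are requested.
#' @param control Optimizer control passed to \code{\link{dm_fit}}.
#' @return A data frame of class \code{dmces_cutoff_table} with columns
#'   \code{n}, \code{kappa}, \code{level}, \code{cutoff}, carrying the
#'   scheme, refit flag and quantile method as attributes (and a warning
#'   flag when \code{reps * level < 5} for the smallest level).
#' @examples
#' \donttest{
#' sc <- dm_scheme(n = 10, error_kappa = 5, reps = 200, seed = 1)
#' dmces_cutoff_table(sc, levels = 0.10)
#' }
#' @export
dmces_cutoff_table <- function(scheme, levels = c(0.10, 0.05, 0.01),
                               refit = TRUE, n = scheme$n,
                               kappa = scheme$error_kappa,
                               control = list()) {
  stopifnot(inherits(scheme, "dm_scheme"))
  if (any(levels <= 0 | levels >= 1))
    stop("levels must lie strictly between 0 and 1", call. = FALSE)
  if (scheme$reps < 100)
    stop("at least 100 replicates are required for a reported percentile",
         call. = FALSE)
  underpowered <- scheme$reps * min(levels) < 5
  if (underpowered)
    warning("fewer than 5 expected tail replicates for the smallest level; ",
            "percentile estimates will be unstable")
  rows <- list()
  for (ni in n) for (ki in kappa) {
    cell <- dm_scheme(ni, ki, scheme$params, scheme$u_mu, scheme$u_kappa,
                      scheme$reps, scheme$seed)
    stats_ <- dmces_null_sample(cell, refit = refit, control = control)
    q <- stats::quantile(stats_, probs = 1 - levels, type = 7, names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(n = ni, kappa = ki, level = levels, cutoff = q)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("dmces_cutoff_table", "data.frame"),
            scheme = scheme, refit = refit,
            quantile_method = "empirical order statistic, linear interpolation (type 7)",
            underpowered = underpowered)
}

# null distribution of DMCEs under a scheme: one value per clean replicate
dmces_null_sample <- function(scheme, refit = TRUE, control = list()) {
  vapply(seq_len(scheme$reps), function(r) {
    x <- dm_simulate(scheme, r)
    dmces(x, refit = refit, control = control)$dmces
  }, numeric(1))
}

#' Power of the DMCEs detection procedure
#'
#' For each contamination degree \eqn{\lambda}, simulates clean datasets,
#' contaminates position \code{d}, runs \code{\link{dmces_detect}} at the
#' supplied (or freshly simulated) cut-off, and scores a success when the
#' statistic exceeds the cut-off \emph{and} the maximising index is the
#' contaminated position (set \code{require_position = FALSE} to score
#' exceedance only).  Power is the success fraction over the replicates.
#'
#' @inheritParams dmces_cutoff_table
#' @param lambdas Contamination degrees, each in \eqn{[0, 1]}.
#' @param level Upper-tail probability of the cut-off (default 5\%).
#' @param cutoff Optional pre-computed cut-off; when \code{NULL} it is
#'   simulated from the scheme at \code{level} first.
#' @param d Contaminated position; defaults to \eqn{\lceil n/2 \rceil}.
#' @param require_position Logical: require the argmax to be the planted
#'   position (the definition of a correct detection)?
#' @return A data frame of class \code{dmces_power} with columns
#'   \code{lambda}, \code{power}; the scheme, level, cut-off and position
#'   are attached as attributes.
#' @examples
#' \donttest{
#' sc <- dm_scheme(n = 10, error_kappa = 20, reps = 100, seed = 2)
#' dmces_power(sc, lambdas = c(0, 1), cutoff = 0.07)
#' }
#' @export
dmces_power <- function(scheme, lambdas = seq(0, 1, by = 0.2), level = 0.05,
                        refit = TRUE, cutoff = NULL, d = NULL,
                        require_position = TRUE, control = list()) {
  stopifnot(inherits(scheme, "dm_scheme"))
  if (any(lambdas < 0 | lambdas > 1))
    stop("lambdas must lie in [0, 1]", call. = FALSE)
  if (is.null(d)) d <- ceiling(scheme$n / 2)
  if (d < 1 || d > scheme$n)
    stop("contamination position out of range", call. = FALSE)
  if (is.null(cutoff)) {
    ct <- dmces_cutoff_table(scheme, levels = level, refit = refit,
                             control = control)
    cutoff <- ct$cutoff[1]
  }
  if (cutoff < 0) stop("cutoff must be non-negative", call. = FALSE)
  power <- vapply(lambdas, function(lam) {
    hits <- vapply(seq_len(scheme$reps), function(r) {
      x <- power_replicate(scheme, r)
      x <- contaminate(x, d, lam)
      rep_ <- dmces(x, refit = refit, control = control)
      rep_$dmces > cutoff && (!require_position || rep_$argmax_index == d)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  structure(data.frame(lambda = lambdas, power = power),
            class = c("dmces_power", "data.frame"),
            scheme = scheme, level = level, cutoff = cutoff, d = d,
            refit = refit, require_position = require_position)
}

# clean replicate on a seed stream disjoint from the calibration stream,
# so power at lambda = 0 is not evaluated on the calibration draws
power_replicate <- function(scheme, rep) {
  s <- replicate_seed(scheme, rep, stream = 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(s)
  u <- rvm(scheme$n, scheme$u_mu, scheme$u_kappa)
  eps <- rvm(scheme$n, 0, scheme$error_kappa)
  angle_pairs(u, wrap_angle(dm_predict(u, scheme$params) + eps))
}

#' Write a simulation product to CSV and JSON
#'
#' Serialises a cut-off table or power result: the rows as plain CSV and,
#' optionally, a JSON document that also carries the scheme metadata
#' (parameters, replicate count, seed, refit flag).
#'
#' @param x A \code{dmces_cutoff_table} or \code{dmces_power} object.
#' @param csv,json Output paths; either may be \code{NULL} to skip.
#' @return \code{x}, invisibly.
#' @export
write_sim_result <- function(x, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  if (!is.null(json)) {
    sc <- attr(x, "scheme")
    meta <- list(n = sc$n, error_kappa = sc$error_kappa,
                 params = unclass(sc$params), u_mu = sc$u_mu,
                 u_kappa = sc$u_kappa, reps = sc$reps, seed = sc$seed,
                 refit = attr(x, "refit"))
    for (a in c("level", "cutoff", "d", "require_position",
                "quantile_method"))
      if (!is.null(attr(x, a))) meta[[a]] <- attr(x, a)
    jsonlite::write_json(list(metadata = meta, rows = as.data.frame(x)),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
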