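#' Mean circular error of a set of residuals
#'
#' Transforms circular residuals \eqn{d_j \in [0, \pi]} to the unit
#' interval and averages them:
#' \deqn{MCEs = \frac{1}{n} \sum_{j=1}^n \sin(d_j / 2).}
#' 0 only for a perfect fit, 1 only when every observation is antipodal to
#' its fitted value.
#'
#' @param residuals Numeric vector of circular distances in \eqn{[0, \pi]}.
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' mces(c(0, pi / 2, pi))
#' @export
mces <- function(residuals) {
  if (length(residuals) < 1) stop("empty residual vector", call. = FALSE)
  if (any(!is.finite(residuals)) || any(residuals < 0 | residuals > pi))
    stop("residuals must be circular distances in [0, pi]", call. = FALSE)
  mean(sin(residuals / 2))
}

#' Row-deletion influence statistic DMCEs
#'
#' Measures how much the mean circular error changes when single
#' observations are removed:
#' \deqn{DMCEs = \max_j |MCEs - MCEs_{(-j)}|,}
#' where \eqn{MCEs_{(-j)}} is the mean circular error of the reduced
#' sample of size \eqn{n - 1}.  With \code{refit = TRUE} (default) the
#' model is refitted on each reduced sample, warm-started from the
#' full-data estimates, so the statistic captures influence on the fit;
#' with \code{refit = FALSE} the full-data parameters are reused and only
#' the residual set shrinks.
#'
#' @param data An \code{\link{angle_pairs}} sample with \eqn{n \ge 5}.
#' @param refit Logical: refit the model after each deletion?
#' @param fit Optional pre-computed full-data \code{\link{dm_fit}}.
#' @param control Optimizer control passed to \code{\link{dm_fit}}.
#' @return An object of class \code{dmces_report} with the full-sample
#'   \code{mces_full}, the leave-one-out values \code{mces_loo}, the
#'   per-observation differences \code{dmces_per_obs}, their maximum
#'   \code{dmces}, the attaining index \code{argmax_index} (smallest index
#'   on ties), and the full fit.  \code{cutoff} and \code{flagged} are
#'   unset until \code{\link{dmces_detect}} is applied.
#' @export
dmces <- function(data, refit = TRUE, fit = NULL, control = list()) {
  stopifnot(inherits(data, "angle_pairs"))
  n <- nrow(data)
  if (n < 5)
    stop("n >= 5 required so every leave-one-out fit keeps n - 1 >= 4",
         call. = FALSE)
  if (is.null(fit)) fit <- dm_fit(data, control = control)
  m_full <- mces(fit$residuals)
  m_loo <- numeric(n)
  for (j in seq_len(n)) {
    red <- angle_pairs(data$u[-j], data$v[-j])
    if (refit) {
      fj <- tryCatch(
        dm_fit(red, init = fit$params, control = control),
        error = function(e)
          stop(sprintf("leave-one-out fit failed after deleting observation %d: %s",
                       j, conditionMessage(e)), call. = FALSE))
      m_loo[j] <- mces(fj$residuals)
    } else {
      m_loo[j] <- mces(circ_dist(red$v, dm_predict(red$u, fit$params)))
    }
  }
  d <- abs(m_full - m_loo)
  structure(list(mces_full = m_full, mces_loo = m_loo, dmces_per_obs = d,
                 dmces = max(d), argmax_index = which.max(d),
                 cutoff = NA_real_, flagged = integer(0),
                 refit = refit, fit = fit, n = n),
            class = "dmces_report")
}

#' Detect an influential observation with DMCEs
#'
#' Computes the row-deletion statistic and flags the maximising
#' observation when \eqn{DMCEs} strictly exceeds the cut-off point (an
#' upper percentile of the statistic under clean-data simulation; see
#' \code{\link{dmces_cutoff_table}}).  At most one observation is flagged
#' per pass, matching the single-outlier procedure.
#'
#' @inheritParams dmces
#' @param cutoff Non-negative cut-off point for the statistic.
#' @return A \code{dmces_report} with \code{cutoff} set and \code{flagged}
#'   holding the argmax index when the statistic exceeds the cut-off
#'   (empty otherwise).
#' @examples
#' \donttest{
#' scheme <- dm_scheme(n = 10, error_kappa = 18, seed = 42)
#' x <- contaminate(dm_simulate(scheme, 1), d = 8, lambda = 1)
#' dmces_detect(x, cutoff = 0.07)
#' }
#' @export
dmces_detect <- function(data, cutoff, refit = TRUE, fit = NULL,
                         control = list()) {
  if (!is.finite(cutoff) || cutoff < 0)
    stop("cutoff must be a non-negative number", call. = FALSE)
  rep <- dmces(data, refit = refit, fit = fit, control = control)
  rep$cutoff <- cutoff
  if (rep$dmces > cutoff) rep$flagged <- rep$argmax_index
  rep
}

#' @export
print.dmces_report <- function(x, digits = 4, ...) {
  cat("DMCEs row-deletion outlier report\n")
  cat(sprintf("  n = %d, refit on deletion: %s\n", x$n, x$refit))
  cat(sprintf("  MCEs (full sample) = %.*f\n", digits, x$mces_full))
  cat(sprintf("  DMCEs = %.*f at observation %d\n", digits, x$dmces,
              x$argmax_index))
  if (!is.na(x$cutoff)) {
    cat(sprintf("  cut-off = %.*f -> %s\n", digits, x$cutoff,
                if (length(x$flagged))
                  sprintf("observation %d flagged as influential", x$flagged)
                else "no observation flagged"))
  }
  invisible(x)
}
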