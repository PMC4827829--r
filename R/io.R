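#' Read a table of paired angles
#'
#' Reads a CSV file with two angle columns named \code{u} and \code{v}
#' (extra columns are kept as row labels when one is named \code{label}).
#' Degrees are converted to radians on read; all angles are wrapped to
#' \eqn{[0, 2\pi)}.
#'
#' @param path Path to a CSV file.
#' @param unit \code{"degrees"} or \code{"radians"}.
#' @return An \code{\link{angle_pairs}} sample, row order preserved.
#' @examples
#' p <- system.file("extdata", "circadian_synthetic.csv", package = "dmces")
#' read_angle_table(p, unit = "degrees")
#' @export
read_angle_table <- function(path, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(d) == 0) stop("empty angle table: ", path, call. = FALSE)
  for (col in c("u", "v")) {
    if (!col %in% names(d))
      stop(sprintf("missing required column '%s' in %s", col, path),
           call. = FALSE)
    val <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d of %s",
                   col, bad[1], path), call. = FALSE)
    d[[col]] <- val
  }
  conv <- if (unit == "degrees") pi / 180 else 1
  labels <- if ("label" %in% names(d)) as.character(d$label) else NULL
  angle_pairs(d$u * conv, d$v * conv, labels = labels)
}

#' Write a table of paired angles
#'
#' Inverse of \code{\link{read_angle_table}}: writes the pairs as CSV in
#' the requested unit (radians are back-converted to degrees when asked).
#'
#' @param data An \code{\link{angle_pairs}} sample.
#' @param path Output CSV path.
#' @param unit \code{"degrees"} or \code{"radians"}.
#' @return \code{path}, invisibly.
#' @export
write_angle_table <- function(data, path, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  stopifnot(inherits(data, "angle_pairs"))
  conv <- if (unit == "degrees") 180 / pi else 1
  out <- data.frame(u = data$u * conv, v = data$v * conv)
  labs <- rownames(data)
  if (!is.null(labs) && !identical(labs, as.character(seq_len(nrow(data)))))
    out <- cbind(label = labs, out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic circadian-style example data
#'
#' Generates a small paired sample emulating a two-period circadian study:
#' \code{n} subjects whose two blood-pressure peak times should agree up
#' to a nearly one-to-one Downs-Mardia relation with highly concentrated
#' errors, plus one planted anti-modal outlier.  This is a synthetic
#' stand-in with the same structure as such studies (n = 10, error
#' concentration about 18, one influential subject), not a real dataset.
#' A frozen copy ships as \code{extdata/circadian_synthetic.csv} (degrees).
#'
#' @param n Number of subjects.
#' @param kappa Error concentration.
#' @param outlier_index Position of the planted outlier (\code{0} for none).
#' @param lambda Degree of contamination of the planted outlier.
#' @param seed Seed for reproducibility.
#' @return An \code{\link{angle_pairs}} sample with attributes
#'   \code{true_params}, \code{outlier_index} and \code{lambda}.
#' @examples
#' make_circadian_synthetic()
#' @export
make_circadian_synthetic <- function(n = 10, kappa = 18, outlier_index = 8,
                                     lambda = 1, seed = 20160411) {
  true <- dm_params(alpha = 16 * pi / 180, beta = 6 * pi / 180, omega = 0.67)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  # peak times cluster in the late-evening quadrant, as circadian blood
  # pressure peaks do
  u <- rvm(n, mu = 310 * pi / 180, kappa = 2.2)
  v <- wrap_angle(dm_predict(u, true) + rvm(n, 0, kappa))
  x <- angle_pairs(u, v, labels = paste0("subject", seq_len(n)))
  if (outlier_index > 0) x <- contaminate(x, outlier_index, lambda)
  attr(x, "true_params") <- true
  attr(x, "outlier_index") <- if (outlier_index > 0) outlier_index else NA_integer_
  attr(x, "lambda") <- lambda
  x
}
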