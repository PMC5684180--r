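# Deterioration-rate law R(p) = A - B * exp(p) ----------------------------

#' Fit the exponential deterioration law
#'
#' Ordinary least squares of the recognition score on the regressor
#' \eqn{e^p} with intercept: \eqn{R(p) = A - B e^p}.  The injury level p is
#' a dimensionless fraction, so over p in \[0, 0.5\] the regressor spans
#' only \[1, 1.65\] and B stays small for gently declining scores.
#'
#' @param data a `data.frame` with injury levels in a column named `injury`
#'   (or `p`) and scores in a column named `R` (or `score`).  Typically the
#'   output of [aggregate_sweep()]; all cells are pooled.
#' @param per_noise when `TRUE` and `data` has a `noise` column, return one
#'   fit per noise level (named list) instead of a pooled fit.
#' @return A `deterioration_fit` (or named list of them): `A`, `B`, their
#'   standard errors `se_A`, `se_B`, `n_points`, residual `rmse`, and the
#'   underlying `lm` model.
#' @export
fit_deterioration <- function(data, per_noise = FALSE) {
  p <- data[["injury"]] %||% data[["p"]]
  r <- data[["R"]] %||% data[["score"]]
  if (is.null(p) || is.null(r))
    stop("`data` must contain columns `injury` (or `p`) and `R` (or `score`)")
  if (per_noise) {
    if (is.null(data[["noise"]])) stop("`per_noise = TRUE` needs a `noise` column")
    fits <- lapply(split(data, data$noise), fit_deterioration)
    return(fits)
  }
  keep <- is.finite(p) & is.finite(r)
  p <- p[keep]; r <- r[keep]
  if (length(unique(p)) < 2L)
    stop("all injury levels identical: singular design, cannot fit A - B*exp(p)")
  m <- lm(r ~ I(exp(p)))
  # suppressWarnings: summary.lm warns on exact (zero-residual) fits
  cf <- coef(m); se <- sqrt(diag(suppressWarnings(vcov(m))))
  structure(list(A = unname(cf[1]), B = -unname(cf[2]),
                 se_A = unname(se[1]), se_B = unname(se[2]),
                 n_points = length(p),
                 rmse = sqrt(mean(residuals(m)^2)),
                 model = m),
            class = "deterioration_fit")
}

#' Predict a recognition score from a deterioration fit
#'
#' @param object a `deterioration_fit`.
#' @param p injury level(s).
#' @param ... unused.
#' @return \eqn{A - B e^p}.
#' @export
predict.deterioration_fit <- function(object, p, ...) {
  object$A - object$B * exp(p)
}

#' @export
print.deterioration_fit <- function(x, ...) {
  cat(sprintf("Deterioration fit: R(p) = %.4f - %.4f * exp(p)\n", x$A, x$B))
  cat(sprintf("  SE(A) = %.4f, SE(B) = %.4f, n = %d points, RMSE = %.4f\n",
              x$se_A, x$se_B, x$n_points, x$rmse))
  invisible(x)
}

#' @importFrom stats vcov residuals
NULL
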