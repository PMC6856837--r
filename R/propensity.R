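## Propensity-score estimation: one logistic model per imputed dataset, with
## the true confounders as covariates, plus the per-subject average score
## used by the Across approach.

#' Fit a propensity-score model
#'
#' Maximum-likelihood logistic regression of exposure on the confounder
#' columns of a completed covariate matrix.
#'
#' @param completion completed covariate matrix (no missing entries).
#' @param z 0/1 exposure vector.
#' @param confounder_cols integer indices of the confounder columns (the
#'   scenario's `spec$confounders`; excludes X1).
#' @return list with `scores` (fitted probabilities, strictly in (0, 1)) and
#'   `coefs` (intercept then confounder coefficients).
#' @export
fit_ps <- function(completion, z, confounder_cols) {
  Xc <- completion[, confounder_cols, drop = FALSE]
  if (anyNA(Xc)) stop("completion contains missing values", call. = FALSE)
  fit <- suppressWarnings(stats::glm.fit(
    x = cbind(`(Intercept)` = 1, Xc), y = z,
    family = stats::binomial(),
    control = list(epsilon = 1e-12, maxit = 100L)))
  e <- fit$fitted.values
  if (!fit$converged || any(e < 1e-12) || any(e > 1 - 1e-12)) {
    stop("propensity model did not converge (possible perfect separation)",
         call. = FALSE)
  }
  list(scores = e, coefs = fit$coefficients)
}

#' Build the per-imputation propensity-score stack
#'
#' Fits one propensity model per completion and stores the per-imputation
#' scores, coefficients, and the per-subject arithmetic mean score (the
#' Across-approach average propensity score). Because the model is refitted
#' in each completion, a subject's score varies across imputations even if
#' none of their own values were imputed.
#'
#' @param stack an `imputed_stack`.
#' @param confounder_cols integer indices of confounder columns.
#' @return an object of class `ps_stack`: list with `scores` (list of m
#'   vectors), `coefs` (list of m vectors), `averaged` (mean score vector).
#' @export
build_ps_stack <- function(stack, confounder_cols) {
  if (!inherits(stack, "imputed_stack")) stop("`stack` must be imputed_stack")
  fits <- lapply(stack$completions, fit_ps, z = stack$z,
                 confounder_cols = confounder_cols)
  scores <- lapply(fits, `[[`, "scores")
  structure(list(
    scores = scores,
    coefs = lapply(fits, `[[`, "coefs"),
    averaged = rowMeans(do.call(cbind, scores)),
    confounder_cols = confounder_cols
  ), class = "ps_stack")
}
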