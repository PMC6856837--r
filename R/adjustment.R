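## Propensity-score adjustment: turn one score vector plus (y, z) into one
## exposure-effect estimate and standard error, by weighting (IPTW or SMRW),
## greedy caliper matching, or decile stratification. Continuous outcomes are
## analysed on the mean-difference scale by (weighted) least squares; binary
## outcomes on the log risk-ratio scale by (weighted) Poisson regression with
## log link. Sandwich variances are implemented directly: the fixed-weight
## HC0 sandwich, and the Lunceford-Davidian stacked-equation sandwich that
## accounts for the propensity score having been estimated.

new_effect_estimate <- function(estimate, se, method, scale, n_used) {
  structure(list(estimate = estimate, se = se, method = method,
                 scale = scale, n_used = as.integer(n_used)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate %s/%s> estimate %.4f (SE %.4f), n_used %d\n",
              x$method, x$scale, x$estimate, x$se, x$n_used))
  invisible(x)
}

#' Inverse-probability-of-treatment weights
#'
#' Exposed subjects receive `1/e`, unexposed `1/(1-e)` (targets the
#' population-average effect).
#'
#' @param e propensity scores, strictly in (0, 1).
#' @param z 0/1 exposure vector.
#' @return a positive weight vector.
#' @export
iptw_weights <- function(e, z) {
  if (any(e <= 0 | e >= 1)) stop("propensity scores must lie in (0, 1)")
  z / e + (1 - z) / (1 - e)
}

#' Standardized-mortality-ratio weights
#'
#' Exposed subjects receive weight 1, unexposed the propensity odds
#' `e/(1-e)` (targets the average effect in the exposed).
#'
#' @inheritParams iptw_weights
#' @return a positive weight vector.
#' @export
smrw_weights <- function(e, z) {
  if (any(e <= 0 | e >= 1)) stop("propensity scores must lie in (0, 1)")
  ifelse(z == 1, 1, e / (1 - e))
}

# Weighted GLM point estimate of the coefficient on z.
# scale "difference": identity-link gaussian (WLS); "logRR": log-link Poisson.
.weighted_fit <- function(y, design, w, scale) {
  if (scale == "difference") {
    fit <- stats::lm.wfit(x = design, y = y, w = w)
    list(coefs = fit$coefficients, mu = drop(design %*% fit$coefficients))
  } else {
    fit <- suppressWarnings(stats::glm.fit(
      x = design, y = y, weights = w, family = stats::poisson(),
      control = list(epsilon = 1e-12, maxit = 100L)))
    if (!fit$converged) stop("weighted Poisson fit did not converge")
    list(coefs = fit$coefficients, mu = fit$fitted.values)
  }
}

# Fixed-weight HC0 sandwich for the weighted GLM above.
# psi_i = w_i (y_i - mu_i) x_i; A = mean(w_i dmu_i x_i x_i').
.robust_vcov <- function(y, design, w, mu, scale) {
  n <- length(y)
  dmu <- if (scale == "difference") 1 else mu
  A <- crossprod(design, design * (w * dmu)) / n
  psi <- design * (w * (y - mu))
  B <- crossprod(psi) / n
  Ainv <- solve(A)
  (Ainv %*% B %*% t(Ainv)) / n
}

#' Weighted exposure-effect estimate
#'
#' Weighted regression of the outcome on exposure: weighted least squares for
#' continuous outcomes (mean difference) and weighted Poisson regression with
#' log link for binary outcomes (log risk ratio). The standard error is the
#' Lunceford-Davidian estimated-propensity sandwich (`se_method = "LD"`,
#' requires `e` and `X_conf`) or the HC0 robust sandwich treating weights as
#' fixed (`se_method = "robust"`).
#'
#' @param y outcome vector; `z` 0/1 exposure; `w` positive weights.
#' @param z exposure vector.
#' @param w weight vector.
#' @param scale `"difference"` or `"logRR"`.
#' @param se_method `"robust"` or `"LD"`.
#' @param e propensity scores (needed for `se_method = "LD"`).
#' @param X_conf confounder matrix the propensity model was fitted on
#'   (needed for `se_method = "LD"`).
#' @param method label stored on the result (`"IPTW"` or `"SMRW"`).
#' @return an `effect_estimate`.
#' @export
estimate_weighted <- function(y, z, w, scale = c("difference", "logRR"),
                              se_method = c("robust", "LD"),
                              e = NULL, X_conf = NULL, method = "IPTW") {
  scale <- match.arg(scale)
  se_method <- match.arg(se_method)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive finite")
  if (all(z == 1) || all(z == 0)) stop("both exposure arms are required")
  if (scale == "logRR" &&
      (sum(y[z == 1]) == 0 || sum(y[z == 0]) == 0)) {
    stop("zero events in one exposure arm; log risk ratio undefined")
  }
  design <- cbind(`(Intercept)` = 1, z = z)
  fit <- .weighted_fit(y, design, w, scale)
  se <- if (se_method == "LD") {
    if (is.null(e) || is.null(X_conf)) {
      stop("se_method = 'LD' requires `e` and `X_conf`")
    }
    ld_se_iptw(y, z, e, X_conf, scale)
  } else {
    sqrt(.robust_vcov(y, design, w, fit$mu, scale)["z", "z"])
  }
  new_effect_estimate(unname(fit$coefs["z"]), se, method, scale, length(y))
}

#' Lunceford-Davidian standard error for IPTW estimates
#'
#' Sandwich variance from the jointly stacked estimating equations: the
#' logistic-regression score equations of the propensity model and the
#' IPTW-weighted moment equations defining the exposure contrast (identity
#' link for mean differences, log link for risk ratios). Because the
#' propensity parameters are estimated jointly, this is typically smaller
#' than the fixed-weight robust sandwich. The Jacobian of the stacked
#' equations is evaluated numerically (central differences).
#'
#' @param y outcome; `z` exposure; `e` fitted propensity scores.
#' @param z exposure vector.
#' @param e fitted propensity scores from a logistic model on `X_conf`.
#' @param X_conf matrix of confounders used in the propensity model.
#' @param scale `"difference"` or `"logRR"`.
#' @return the standard error of the coefficient on `z`.
#' @export
ld_se_iptw <- function(y, z, e, X_conf, scale = c("difference", "logRR")) {
  scale <- match.arg(scale)
  X_conf <- as.matrix(X_conf)
  n <- length(y)
  D_ps <- cbind(1, X_conf)
  theta <- fit_ps(cbind(X_conf), z, seq_len(ncol(X_conf)))$coefs
  w <- iptw_weights(e, z)
  design <- cbind(1, z)
  fit <- .weighted_fit(y, design, w, scale)
  params <- c(theta, fit$coefs)
  q <- length(theta)
  d <- q + 2L

  psi_mat <- function(par) {
    eta <- drop(D_ps %*% par[1:q])
    ee <- expit(eta)
    ww <- z / ee + (1 - z) / (1 - ee)
    lp <- drop(design %*% par[(q + 1):d])
    mu <- if (scale == "difference") lp else exp(lp)
    cbind(D_ps * (z - ee), design * (ww * (y - mu)))
  }

  B <- crossprod(psi_mat(params)) / n
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    h <- 1e-6 * max(1, abs(params[j]))
    up <- dn <- params
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (colMeans(psi_mat(up)) - colMeans(psi_mat(dn))) / (2 * h)
  }
  Jinv <- solve(J)
  V <- (Jinv %*% B %*% t(Jinv)) / n
  sqrt(V[d, d])
}

#' Matching caliper
#'
#' `method = "logit_sd"` (default): `width_multiplier` times the standard
#' deviation of the logit propensity score, on the logit scale.
#' `method = "youden"`: a reconstruction of a Youden's-J-based rule — the
#' caliper is `(1 - J*) * SD(e)` on the probability scale, where `J*` is the
#' maximum of Youden's J over thresholds classifying exposure from the score;
#' well-separated exposure groups (large `J*`) thus force tighter matches.
#' The underlying published rule is not fully specified, so treat this mode
#' as a documented reconstruction.
#'
#' @param e propensity scores; `z` 0/1 exposure.
#' @param z exposure vector.
#' @param method `"logit_sd"` or `"youden"`.
#' @param width_multiplier multiplier for the `logit_sd` rule (default 0.2).
#' @return a positive scalar with attribute `scale` (`"logit"` or `"ps"`),
#'   the scale on which matching distances should be measured.
#' @export
compute_caliper <- function(e, z, method = c("logit_sd", "youden"),
                            width_multiplier = 0.2) {
  method <- match.arg(method)
  if (stats::sd(e) == 0) stop("propensity scores are constant")
  if (method == "logit_sd") {
    cal <- width_multiplier * stats::sd(logit(e))
    attr(cal, "scale") <- "logit"
  } else {
    thresholds <- sort(unique(e))
    jvals <- vapply(thresholds, function(c0) {
      mean(e[z == 1] >= c0) - mean(e[z == 0] >= c0)
    }, numeric(1))
    cal <- (1 - max(jvals)) * stats::sd(e)
    if (cal <= 0) stop("degenerate Youden caliper (perfect separation)")
    attr(cal, "scale") <- "ps"
  }
  cal
}

#' Greedy one-to-one caliper matching without replacement
#'
#' Exposed subjects are processed in a random order (drawn from the current
#' RNG state); each is paired with the nearest not-yet-used unexposed subject
#' whose distance on the matching scale is within the caliper. Exposed
#' subjects with no admissible partner are dropped; no unexposed subject is
#' reused.
#'
#' @param e propensity scores; `z` 0/1 exposure.
#' @param z exposure vector.
#' @param caliper positive caliper, from [compute_caliper()] (its `scale`
#'   attribute selects the matching scale) or a plain number.
#' @param match_scale `"logit"` or `"ps"`; overrides the caliper attribute.
#' @return integer matrix with columns `exposed`, `control`, one row per
#'   matched pair (possibly zero rows), with the processing order of exposed
#'   subjects stored in attribute `order`.
#' @export
greedy_match <- function(e, z, caliper, match_scale = NULL) {
  if (caliper <= 0) stop("caliper must be positive")
  scale <- match_scale %||% attr(caliper, "scale") %||% "logit"
  v <- if (scale == "logit") logit(e) else e
  exposed <- which(z == 1)
  controls <- which(z == 0)
  ord <- exposed[sample.int(length(exposed))]
  available <- rep(TRUE, length(controls))
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("exposed", "control")))
  for (i in ord) {
    idx <- which(available)
    if (length(idx) == 0) break
    dd <- abs(v[controls[idx]] - v[i])
    best <- which.min(dd)
    if (dd[best] <= caliper) {
      pairs <- rbind(pairs, c(i, controls[idx[best]]))
      available[idx[best]] <- FALSE
    }
  }
  attr(pairs, "order") <- ord
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exposure effect in the matched sample
#'
#' Regression of the outcome on exposure restricted to matched subjects:
#' ordinary least squares (model-based SE) for continuous outcomes, Poisson
#' regression with HC0 robust SE for binary outcomes.
#'
#' @param y outcome; `z` exposure; `pairs` matrix from [greedy_match()].
#' @param z exposure vector.
#' @param pairs two-column matrix of matched index pairs.
#' @param scale `"difference"` or `"logRR"`.
#' @return an `effect_estimate` with `n_used = 2 * nrow(pairs)`.
#' @export
estimate_matched <- function(y, z, pairs, scale = c("difference", "logRR")) {
  scale <- match.arg(scale)
  if (nrow(pairs) < 2) stop("fewer than 2 matched pairs")
  idx <- c(pairs[, 1], pairs[, 2])
  ys <- y[idx]
  zs <- z[idx]
  design <- cbind(`(Intercept)` = 1, z = zs)
  if (scale == "difference") {
    fit <- stats::lm.fit(x = design, y = ys)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (length(ys) - 2L)
    XtXinv <- chol2inv(chol(crossprod(design)))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    est <- unname(fit$coefficients["z"])
  } else {
    if (sum(ys[zs == 1]) == 0 || sum(ys[zs == 0]) == 0) {
      stop("zero events in one arm of the matched sample")
    }
    fit <- .weighted_fit(ys, design, rep(1, length(ys)), "logRR")
    se <- sqrt(.robust_vcov(ys, design, rep(1, length(ys)), fit$mu,
                            "logRR")["z", "z"])
    est <- unname(fit$coefs["z"])
  }
  new_effect_estimate(est, se, "MATCH", scale, 2L * nrow(pairs))
}

#' Stratified exposure effect
#'
#' Subjects are binned into `n_strata` sample quantile strata of the
#' propensity score (boundary ties go to the lower stratum) and the outcome
#' is regressed on exposure plus stratum indicators: ordinary least squares
#' for continuous outcomes, Poisson with HC0 robust SE for binary outcomes.
#' Strata containing only one exposure arm are dropped with a warning.
#'
#' @param y outcome; `z` exposure; `e` propensity scores.
#' @param z exposure vector.
#' @param e propensity scores.
#' @param n_strata number of strata (default 10, deciles).
#' @param scale `"difference"` or `"logRR"`.
#' @return an `effect_estimate`.
#' @export
estimate_stratified <- function(y, z, e, n_strata = 10L,
                                scale = c("difference", "logRR")) {
  scale <- match.arg(scale)
  if (length(y) < n_strata) stop("fewer subjects than strata")
  breaks <- unique(stats::quantile(e, probs = seq(0, 1, length.out = n_strata + 1)))
  s <- cut(e, breaks = breaks, include.lowest = TRUE, right = TRUE)
  keep_levels <- names(which(tapply(z, s, function(zz) {
    any(zz == 1) && any(zz == 0)
  })))
  if (length(keep_levels) < nlevels(s)) {
    warning(sprintf("dropping %d stratum/strata with a single exposure arm",
                    nlevels(s) - length(keep_levels)))
  }
  keep <- s %in% keep_levels
  s <- droplevels(s[keep])
  ys <- y[keep]
  zs <- z[keep]
  S <- stats::model.matrix(~s)[, -1, drop = FALSE]
  design <- cbind(`(Intercept)` = 1, z = zs, S)
  if (scale == "difference") {
    fit <- stats::lm.fit(x = design, y = ys)
    sigma2 <- sum(fit$residuals^2) / (length(ys) - ncol(design))
    XtXinv <- chol2inv(chol(crossprod(design)))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    est <- unname(fit$coefficients["z"])
  } else {
    fit <- .weighted_fit(ys, design, rep(1, length(ys)), "logRR")
    se <- sqrt(.robust_vcov(ys, design, rep(1, length(ys)), fit$mu,
                            "logRR")["z", "z"])
    est <- unname(fit$coefs["z"])
  }
  new_effect_estimate(est, se, "STRAT", scale, length(ys))
}
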