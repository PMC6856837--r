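## Scenario definitions and synthetic-data generation.
##
## Eight scenarios share one generative template: p covariates, multivariate
## normal; a binary exposure assigned by a logistic model in the confounders;
## a continuous (linear) or binary (logistic) outcome; and missingness imposed
## on confounder values only, MAR (driven by the fully observed covariate X1
## and the outcome) or MNAR (driven by the partially observed value itself and
## the outcome). Intercepts are calibrated by Monte Carlo so that exposure
## prevalence, event rate and missingness rate hit their design targets.

# Design grid: X1 affects the outcome only (never a confounder); X2..Xp are
# confounders. The correlated scenarios give (X2, X3, X4) pairwise
# correlation 0.5; X1 is always independent standard normal.
.scenario_table <- function() {
  l2 <- log(2)
  list(
    S1 = list(p = 2L, beta = c(-1, 1), alpha = c(0, l2), corr = FALSE,
              outcome = "continuous", mechanism = "MAR"),
    S2 = list(p = 4L, beta = c(-1, 1, -1, -1), alpha = c(0, l2, l2, l2),
              corr = FALSE, outcome = "continuous", mechanism = "MAR"),
    S3 = list(p = 4L, beta = c(-1, 1, -1, -1), alpha = c(0, l2, l2, l2),
              corr = TRUE, outcome = "continuous", mechanism = "MAR"),
    S4 = list(p = 4L, beta = c(-1, 1, -1, -1), alpha = c(0, l2, -l2, l2),
              corr = TRUE, outcome = "continuous", mechanism = "MAR"),
    S5 = list(p = 4L, beta = c(-1, 1, -1, -1),
              alpha = c(0, log(1.65), log(1.65), log(1.65)), corr = TRUE,
              outcome = "continuous", mechanism = "MAR"),
    S6 = list(p = 4L, beta = c(-1, 1, -1, -1),
              alpha = c(0, log(1.25), log(1.25), log(1.25)), corr = TRUE,
              outcome = "continuous", mechanism = "MAR"),
    # S7 and S8 reuse the S6 baseline (weak confounding, correlated).
    S7 = list(p = 4L, beta = c(-1, 1, -1, -1),
              alpha = c(0, log(1.25), log(1.25), log(1.25)), corr = TRUE,
              outcome = "binary", mechanism = "MAR"),
    S8 = list(p = 4L, beta = c(-1, 1, -1, -1),
              alpha = c(0, log(1.25), log(1.25), log(1.25)), corr = TRUE,
              outcome = "continuous", mechanism = "MNAR")
  )
}

#' Construct a simulation scenario
#'
#' Builds the generative specification for one of the eight study scenarios:
#' covariate law, outcome-model coefficients `beta`, exposure-model
#' coefficients `alpha` (zero for the non-confounder X1), the true exposure
#' effect, and the design targets for exposure prevalence and per-confounder
#' missingness. Intercepts (`alpha0`, `beta0` for binary outcomes, `gamma`)
#' are left uncalibrated; fill them with [calibrate_scenario()].
#'
#' @param scenario_id one of `"S1"`..`"S8"`.
#' @param exposure_prevalence_target target proportion exposed (the study
#'   design uses 0.5 for weighting/stratification and 0.1 for SMRW/matching).
#' @param missing_rate_target target marginal missingness proportion per
#'   confounder (the study design uses 0.10, 0.25, 0.30, 0.35, 0.50, 0.75).
#' @param outcome_type `"continuous"` or `"binary"`; defaults to the
#'   scenario's canonical type (binary only in S7).
#' @param missing_mechanism `"MAR"` or `"MNAR"`; defaults to the scenario's
#'   canonical mechanism (MNAR only in S8).
#' @param n dataset size per replicate.
#' @param m number of imputations.
#' @param n_reps number of replicate datasets.
#' @return an object of class `scenario_spec`.
#' @examples
#' sp <- make_scenario("S1")
#' sp$alpha # c(0, log(2))
#' @export
make_scenario <- function(scenario_id,
                          exposure_prevalence_target = 0.5,
                          missing_rate_target = 0.25,
                          outcome_type = NULL,
                          missing_mechanism = NULL,
                          n = 1000L, m = 10L, n_reps = 1000L) {
  tab <- .scenario_table()
  if (!scenario_id %in% names(tab)) {
    stop("unknown scenario id: ", scenario_id, call. = FALSE)
  }
  row <- tab[[scenario_id]]
  outcome_type <- if (is.null(outcome_type)) row$outcome else
    match.arg(outcome_type, c("continuous", "binary"))
  missing_mechanism <- if (is.null(missing_mechanism)) row$mechanism else
    match.arg(missing_mechanism, c("MAR", "MNAR"))
  if (outcome_type != row$outcome || missing_mechanism != row$mechanism) {
    stop(sprintf(
      "scenario %s is defined with a %s outcome and %s missingness",
      scenario_id, row$outcome, row$mechanism), call. = FALSE)
  }
  stopifnot_prob(exposure_prevalence_target, "exposure_prevalence_target")
  stopifnot_prob(missing_rate_target, "missing_rate_target")

  p <- row$p
  Sigma <- diag(p)
  if (row$corr) Sigma[2:p, 2:p][row(diag(p - 1)) != col(diag(p - 1))] <- 0.5
  spec <- structure(list(
    scenario_id = scenario_id,
    p = p,
    cov_mean = rep(0, p),
    cov_corr = Sigma,
    beta = row$beta,
    alpha = row$alpha,
    beta_z = if (outcome_type == "continuous") 2 else log(2),
    outcome_type = outcome_type,
    missing_mechanism = missing_mechanism,
    exposure_prevalence_target = exposure_prevalence_target,
    missing_rate_target = missing_rate_target,
    confounders = which(row$alpha != 0),
    alpha0 = NA_real_,
    beta0 = if (outcome_type == "continuous") 0 else NA_real_,
    gamma = NA_real_,
    rr_true = NA_real_,
    n = as.integer(n), m = as.integer(m), n_reps = as.integer(n_reps)
  ), class = "scenario_spec")
  stopifnot(isSymmetric(spec$cov_corr),
            all(diag(spec$cov_corr) == 1),
            all(eigen(spec$cov_corr, symmetric = TRUE,
                      only.values = TRUE)$values > 0))
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec %s> p=%d, %s outcome, %s missingness\n",
              x$scenario_id, x$p, x$outcome_type, x$missing_mechanism))
  cat(sprintf("  alpha = (%s), beta = (%s), beta_z = %.4g\n",
              paste(signif(x$alpha, 4), collapse = ", "),
              paste(signif(x$beta, 4), collapse = ", "), x$beta_z))
  cat(sprintf("  targets: prevalence %.2f, missing %.2f; calibrated: %s\n",
              x$exposure_prevalence_target, x$missing_rate_target,
              if (is_calibrated(x)) "yes" else "no"))
  invisible(x)
}

#' Is a scenario fully calibrated?
#' @param spec a `scenario_spec`.
#' @return `TRUE` when all required intercepts have been set.
#' @export
is_calibrated <- function(spec) {
  !is.na(spec$alpha0) && !is.na(spec$gamma) && !is.na(spec$beta0)
}

#' Draw the covariate matrix
#'
#' Rows are i.i.d. multivariate normal with mean zero and the scenario's
#' correlation structure: X1 standard normal independent of the rest; in the
#' correlated scenarios (X2, X3, X4) share pairwise correlation 0.5.
#'
#' @param spec a `scenario_spec`.
#' @param n number of rows.
#' @return an `n` by `p` numeric matrix with columns `x1`..`xp`.
#' @export
draw_covariates <- function(spec, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  Z <- matrix(stats::rnorm(n * spec$p), n, spec$p)
  X <- Z %*% chol(spec$cov_corr)
  X <- sweep(X, 2, spec$cov_mean, `+`)
  colnames(X) <- paste0("x", seq_len(spec$p))
  X
}

# Root-find an intercept c so that mean(plogis(c + lp)) == target, on a fixed
# Monte Carlo draw of linear predictors. Monotone in c, so uniroot is exact up
# to its tolerance; the draw size controls the Monte Carlo error.
.calibrate_intercept <- function(lp, target, lower = -30, upper = 30) {
  f <- function(c0) mean(expit(c0 + lp)) - target
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

#' Calibrate the exposure-model intercept
#'
#' Finds `alpha0` such that the marginal exposure prevalence
#' `E[expit(alpha0 + alpha'x)]` equals the scenario's target, by root-finding
#' on a large Monte Carlo draw of covariates. Deterministic given the RNG
#' state on entry.
#'
#' @param spec a `scenario_spec`.
#' @param n_mc Monte Carlo sample size for the prevalence estimate.
#' @return the calibrated intercept (a single number).
#' @export
calibrate_exposure_intercept <- function(spec, n_mc = 1e6) {
  stopifnot_prob(spec$exposure_prevalence_target, "exposure_prevalence_target")
  lp <- drop(draw_covariates(spec, n_mc) %*% spec$alpha)
  .calibrate_intercept(lp, spec$exposure_prevalence_target)
}

#' Draw exposure status
#'
#' @param spec a calibrated `scenario_spec` (`alpha0` set).
#' @param X covariate matrix from [draw_covariates()].
#' @return a 0/1 integer vector, `z[i] ~ Bernoulli(expit(alpha0 + alpha'x_i))`.
#' @export
draw_exposure <- function(spec, X) {
  if (is.na(spec$alpha0)) stop("alpha0 is not calibrated", call. = FALSE)
  pz <- expit(spec$alpha0 + drop(X %*% spec$alpha))
  as.integer(stats::rbinom(nrow(X), 1L, pz))
}

#' Simulate a continuous outcome
#'
#' `y = beta0 + X beta + beta_z z + eps` with `eps ~ N(0, 1)`. The noise can
#' be disabled for exact plug-in checks.
#'
#' @param spec a `scenario_spec` with `outcome_type = "continuous"`.
#' @param X covariate matrix; `z` 0/1 exposure vector.
#' @param z exposure vector.
#' @param noise_sd standard deviation of the residual noise (default 1).
#' @return numeric outcome vector.
#' @export
simulate_continuous_outcome <- function(spec, X, z, noise_sd = 1) {
  if (spec$outcome_type != "continuous") {
    stop("spec has a binary outcome", call. = FALSE)
  }
  if (nrow(X) != length(z) || ncol(X) != length(spec$beta)) {
    stop("dimension mismatch between X, beta and z", call. = FALSE)
  }
  eps <- if (noise_sd > 0) stats::rnorm(nrow(X), 0, noise_sd) else 0
  spec$beta0 + drop(X %*% spec$beta) + spec$beta_z * z + eps
}

#' Calibrate the binary-outcome intercept
#'
#' Finds `beta0` so that the marginal event rate of the *observed* outcome
#' (accounting for the exposure distribution and its `ln 2` log-odds effect)
#' equals `target`, by Monte Carlo root-finding.
#'
#' @param spec a calibrated-exposure `scenario_spec` with binary outcome.
#' @param target target event rate (default 0.5, the study design).
#' @param n_mc Monte Carlo sample size.
#' @return the calibrated intercept.
#' @export
calibrate_outcome_intercept <- function(spec, target = 0.5, n_mc = 1e6) {
  if (spec$outcome_type != "binary") stop("outcome is continuous", call. = FALSE)
  if (is.na(spec$alpha0)) stop("calibrate alpha0 first", call. = FALSE)
  X <- draw_covariates(spec, n_mc)
  z <- draw_exposure(spec, X)
  lp <- drop(X %*% spec$beta) + spec$beta_z * z
  .calibrate_intercept(lp, target)
}

#' Simulate a binary outcome with both potential outcomes
#'
#' The linear predictor is `eta = beta0 + X beta`; potential outcomes are
#' independent Bernoulli draws with `P(y0=1) = expit(eta)` and
#' `P(y1=1) = expit(eta + ln 2)`; the observed outcome is selected by the
#' realized exposure (consistency).
#'
#' @inheritParams simulate_continuous_outcome
#' @return a list with integer vectors `y`, `y_pot0`, `y_pot1`.
#' @export
simulate_binary_outcome <- function(spec, X, z) {
  if (spec$outcome_type != "binary") stop("outcome is continuous", call. = FALSE)
  if (is.na(spec$beta0)) stop("beta0 is not calibrated", call. = FALSE)
  eta <- spec$beta0 + drop(X %*% spec$beta)
  y0 <- as.integer(stats::rbinom(length(eta), 1L, expit(eta)))
  y1 <- as.integer(stats::rbinom(length(eta), 1L, expit(eta + spec$beta_z)))
  list(y = ifelse(z == 1L, y1, y0), y_pot0 = y0, y_pot1 = y1)
}

#' True marginal risk ratio from a potential-outcomes super-population
#'
#' Simulates `N` subjects with both potential outcomes and returns
#' `mean(y_pot1) / mean(y_pot0)` — the marginal (population-averaged) risk
#' ratio that the binary-outcome estimators target. Compute once per scenario
#' with a fixed seed and reuse as the estimand.
#'
#' @param spec a calibrated binary-outcome `scenario_spec`.
#' @param N super-population size (default 1e6).
#' @return the true marginal risk ratio.
#' @export
true_marginal_rr <- function(spec, N = 1e6) {
  X <- draw_covariates(spec, N)
  z <- draw_exposure(spec, X)
  out <- simulate_binary_outcome(spec, X, z)
  p0 <- mean(out$y_pot0)
  if (p0 == 0) stop("no events under no exposure; RR undefined", call. = FALSE)
  mean(out$y_pot1) / p0
}

#' Calibrate the missingness intercept
#'
#' Finds `gamma` so that the marginal per-confounder missingness probability —
#' `expit(gamma + ln(1.25) x1 + ln(1.75) y)` under MAR, with the confounder's
#' own value in place of `x1` under MNAR — equals the scenario's target rate,
#' by Monte Carlo root-finding on a large simulated complete dataset.
#'
#' @param spec a `scenario_spec` with `alpha0` (and `beta0` if binary) set.
#' @param n_mc Monte Carlo sample size.
#' @return the calibrated intercept.
#' @export
calibrate_missingness_intercept <- function(spec, n_mc = 1e6) {
  stopifnot_prob(spec$missing_rate_target, "missing_rate_target")
  X <- draw_covariates(spec, n_mc)
  z <- draw_exposure(spec, X)
  y <- if (spec$outcome_type == "continuous") {
    simulate_continuous_outcome(spec, X, z)
  } else {
    simulate_binary_outcome(spec, X, z)$y
  }
  drivers <- if (spec$missing_mechanism == "MAR") {
    # one column: the MAR rate is the same for every confounder
    X[, 1, drop = FALSE]
  } else {
    X[, spec$confounders, drop = FALSE]
  }
  lp <- log(1.25) * drivers + log(1.75) * y  # column-wise recycling of y
  .calibrate_intercept(as.vector(lp), spec$missing_rate_target)
}

#' Calibrate all scenario intercepts
#'
#' Convenience wrapper: fills `alpha0`, `beta0` (binary outcomes, targeting a
#' 50% event rate), `gamma`, and the true marginal risk ratio `rr_true`
#' (binary outcomes). Deterministic given the RNG state on entry.
#'
#' @param spec a `scenario_spec`.
#' @param n_mc Monte Carlo sample size for each calibration.
#' @param event_rate_target event-rate target for binary outcomes.
#' @return the calibrated `scenario_spec`.
#' @export
calibrate_scenario <- function(spec, n_mc = 1e6, event_rate_target = 0.5) {
  spec$alpha0 <- calibrate_exposure_intercept(spec, n_mc)
  if (spec$outcome_type == "binary") {
    spec$beta0 <- calibrate_outcome_intercept(spec, event_rate_target, n_mc)
    spec$rr_true <- true_marginal_rr(spec, max(n_mc, 1e6))
  }
  spec$gamma <- calibrate_missingness_intercept(spec, n_mc)
  spec
}

#' True effect on the estimation scale
#'
#' The mean difference `beta_z` for continuous outcomes; `log(rr_true)` for
#' binary outcomes (estimators work on the log risk-ratio scale).
#'
#' @param spec a calibrated `scenario_spec`.
#' @return a single number.
#' @export
true_effect <- function(spec) {
  if (spec$outcome_type == "continuous") spec$beta_z else log(spec$rr_true)
}

#' Simulate a complete dataset
#'
#' @param spec a calibrated `scenario_spec`.
#' @param n dataset size (defaults to `spec$n`).
#' @return an object of class `complete_data`: list with `X`, `z`, `y` and,
#'   for binary outcomes, `y_pot0`, `y_pot1`.
#' @export
simulate_complete <- function(spec, n = spec$n) {
  X <- draw_covariates(spec, n)
  z <- draw_exposure(spec, X)
  if (spec$outcome_type == "continuous") {
    out <- list(X = X, z = z, y = simulate_continuous_outcome(spec, X, z))
  } else {
    yy <- simulate_binary_outcome(spec, X, z)
    out <- list(X = X, z = z, y = yy$y, y_pot0 = yy$y_pot0, y_pot1 = yy$y_pot1)
  }
  structure(out, class = "complete_data")
}

#' Impose missingness on the confounders
#'
#' Draws an independent Bernoulli missingness indicator for each confounder
#' entry. Under MAR the probability is `expit(gamma + ln(1.25) x1 + ln(1.75) y)`
#' (depends on the always-observed X1 and the outcome); under MNAR the
#' confounder's own value replaces `x1`. Non-confounder columns, exposure and
#' outcome are never masked.
#'
#' @param data a `complete_data` object.
#' @param spec the calibrated `scenario_spec` that generated it.
#' @return an object of class `observed_data`: the complete data plus a 0/1
#'   `mask` matrix (1 = missing) and an `X_obs` copy with `NA` at masked
#'   entries.
#' @export
impose_missingness <- function(data, spec) {
  if (is.na(spec$gamma)) stop("gamma is not calibrated", call. = FALSE)
  n <- nrow(data$X)
  mask <- matrix(0L, n, spec$p, dimnames = dimnames(data$X))
  for (j in spec$confounders) {
    driver <- if (spec$missing_mechanism == "MAR") data$X[, 1] else data$X[, j]
    pm <- expit(spec$gamma + log(1.25) * driver + log(1.75) * data$y)
    mask[, j] <- stats::rbinom(n, 1L, pm)
  }
  X_obs <- data$X
  X_obs[mask == 1L] <- NA_real_
  structure(c(unclass(data), list(mask = mask, X_obs = X_obs)),
            class = "observed_data")
}

#' Simulate an observed (incomplete) dataset
#'
#' @inheritParams simulate_complete
#' @return an `observed_data` object.
#' @export
simulate_observed <- function(spec, n = spec$n) {
  impose_missingness(simulate_complete(spec, n), spec)
}

#' Export an observed dataset as CSV
#'
#' Writes columns `x1..xp, z, y` with masked entries as empty fields, for
#' cross-checking in other environments.
#'
#' @param obs an `observed_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observed_csv <- function(obs, path) {
  df <- as.data.frame(obs$X_obs)
  df$z <- obs$z
  df$y <- obs$y
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
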