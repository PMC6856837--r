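## Multiple imputation by chained equations for incomplete Gaussian
## confounders. Each incomplete column is imputed from a Bayesian linear
## regression on all other covariates, the exposure and the outcome, with
## parameter draws from the approximate posterior and a predictive noise draw
## (proper imputation), so that between-imputation variability reflects
## genuine posterior uncertainty.

# One proper Bayesian draw for a single incomplete column.
# D_obs/D_mis: design matrices (with intercept); t_obs: observed responses.
.bayes_lm_draw <- function(D_obs, t_obs, D_mis) {
  qr_d <- qr(D_obs)
  if (qr_d$rank < ncol(D_obs)) {
    stop("rank-deficient imputation model design", call. = FALSE)
  }
  beta_hat <- qr.coef(qr_d, t_obs)
  resid <- t_obs - drop(D_obs %*% beta_hat)
  df <- nrow(D_obs) - ncol(D_obs)
  sigma2 <- sum(resid^2) / stats::rchisq(1L, df)
  # beta* ~ N(beta_hat, sigma2 (D'D)^-1) via the R factor of the QR
  R <- qr.R(qr_d)
  beta_star <- beta_hat + sqrt(sigma2) *
    backsolve(R, stats::rnorm(ncol(D_obs)))
  drop(D_mis %*% beta_star) + stats::rnorm(nrow(D_mis), 0, sqrt(sigma2))
}

#' Multiple imputation by chained equations
#'
#' Imputes the masked confounder entries of an observed dataset `m` times.
#' Within each completion, missing values are initialized by resampling each
#' variable's observed values, then updated over `n_cycles` sweeps; in each
#' sweep every incomplete confounder is re-imputed from a Bayesian linear
#' regression on all other covariates, the exposure and the outcome (the
#' analysis-model variables are all in the imputation model). Completions are
#' mutually independent given the RNG state on entry.
#'
#' @param obs an `observed_data` object (missingness confined to confounders;
#'   `z` and `y` complete).
#' @param m number of imputations (at least 2).
#' @param n_cycles chained-equation sweeps per completion.
#' @return an object of class `imputed_stack`: list with `completions` (list
#'   of `m` completed covariate matrices), `z`, `y`, `m`, and `mask`.
#' @export
mice_impute <- function(obs, m = 10L, n_cycles = 10L) {
  if (!inherits(obs, "observed_data")) stop("`obs` must be observed_data")
  if (m < 2L) stop("m must be at least 2", call. = FALSE)
  mask <- obs$mask
  n <- nrow(mask)
  incomplete <- which(colSums(mask) > 0L)
  if (any(colSums(mask) == n)) {
    stop("column(s) entirely missing: ",
         paste(colnames(mask)[colSums(mask) == n], collapse = ", "),
         call. = FALSE)
  }
  extra <- cbind(z = as.numeric(obs$z), y = as.numeric(obs$y))

  completions <- vector("list", m)
  for (k in seq_len(m)) {
    Xk <- obs$X_obs
    # initialize masked entries from the observed marginal of each column
    for (j in incomplete) {
      mis <- mask[, j] == 1L
      Xk[mis, j] <- sample(Xk[!mis, j], sum(mis), replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (j in incomplete) {
        mis <- mask[, j] == 1L
        D <- cbind(1, Xk[, -j, drop = FALSE], extra)
        Xk[mis, j] <- .bayes_lm_draw(D[!mis, , drop = FALSE],
                                     Xk[!mis, j], D[mis, , drop = FALSE])
      }
    }
    completions[[k]] <- Xk
  }
  structure(list(completions = completions, z = obs$z, y = obs$y,
                 m = as.integer(m), mask = mask),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("<imputed_stack> m=%d completions of %d x %d (%.1f%% imputed)\n",
              x$m, nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}
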