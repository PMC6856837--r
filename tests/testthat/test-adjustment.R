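# Weights, weighted estimators, sandwich variances, matching, stratification.

test_that("IPTW and SMRW weights follow their definitions", {
  expect_equal(iptw_weights(0.5, 1L), 2)
  expect_equal(iptw_weights(0.25, 0L), 1 / 0.75)
  expect_equal(smrw_weights(0.4, 1L), 1)
  expect_equal(smrw_weights(0.5, 0L), 1)
  expect_equal(smrw_weights(2 / 3, 0L), 2)
  expect_error(iptw_weights(0, 1L), "in \\(0, 1\\)")
  expect_error(smrw_weights(1, 0L), "in \\(0, 1\\)")
})

test_that("IPTW weights have the Horvitz-Thompson sum property", {
  sp <- cached_spec("S1")
  set.seed(81)
  X <- draw_covariates(sp, 1e5)
  e_true <- plogis(sp$alpha0 + drop(X %*% sp$alpha))
  z <- rbinom(1e5, 1, e_true)
  w <- iptw_weights(e_true, z)
  expect_lt(abs(sum(w[z == 1]) / 1e5 - 1), 0.02)
  expect_lt(abs(sum(w[z == 0]) / 1e5 - 1), 0.02)
})

test_that("weighted regression equals closed-form weighted mean contrasts", {
  set.seed(82)
  n <- 500
  y <- rnorm(n)
  z <- rbinom(n, 1, 0.4)
  e <- runif(n, 0.1, 0.9)
  w <- iptw_weights(e, z)

  est <- estimate_weighted(y, z, w, "difference")
  closed <- sum(w * z * y) / sum(w * z) - sum(w * (1 - z) * y) / sum(w * (1 - z))
  expect_lt(abs(est$estimate - closed), 1e-8)

  # unit weights: difference of arm means
  est1 <- estimate_weighted(y, z, rep(1, n), "difference")
  expect_lt(abs(est1$estimate - (mean(y[z == 1]) - mean(y[z == 0]))), 1e-10)

  # binary, unit weights: Poisson log-link gives the log ratio of proportions
  yb <- rbinom(n, 1, 0.5)
  estb <- estimate_weighted(yb, z, rep(1, n), "logRR")
  expect_lt(abs(exp(estb$estimate) - mean(yb[z == 1]) / mean(yb[z == 0])), 1e-8)

  expect_error(estimate_weighted(y, rep(1L, n), w, "difference"), "both exposure arms")
  expect_error(estimate_weighted(rep(0, n), z, w, "logRR"), "zero events")
  expect_error(estimate_weighted(y, z, rep(-1, n), "difference"), "positive")
})

test_that("the fixed-weight HC0 sandwich matches an independent implementation", {
  skip_if_not_installed("sandwich")
  set.seed(83)
  n <- 400
  z <- rbinom(n, 1, 0.5)
  yb <- rbinom(n, 1, plogis(-0.5 + 0.3 * z))
  fit <- glm(yb ~ z, family = poisson())
  se_ref <- sqrt(sandwich::vcovHC(fit, type = "HC0")["z", "z"])
  est <- estimate_weighted(yb, z, rep(1, n), "logRR", se_method = "robust")
  expect_equal(est$se, se_ref, tolerance = 1e-6)
})

test_that("LD sandwich matches the bootstrap and dominates the fixed-weight SE", {
  sp <- cached_spec("S1")
  set.seed(84)
  d <- simulate_complete(sp, 500)
  ps <- fit_ps(d$X, d$z, sp$confounders)
  Xc <- d$X[, sp$confounders, drop = FALSE]
  ld <- ld_se_iptw(d$y, d$z, ps$scores, Xc, "difference")

  # nonparametric bootstrap that refits the propensity model each draw
  set.seed(85)
  boot <- replicate(2000, {
    i <- sample.int(500, replace = TRUE)
    psb <- fit_ps(d$X[i, , drop = FALSE], d$z[i], sp$confounders)
    w <- iptw_weights(psb$scores, d$z[i])
    yb <- d$y[i]; zb <- d$z[i]
    sum(w * zb * yb) / sum(w * zb) -
      sum(w * (1 - zb) * yb) / sum(w * (1 - zb))
  })
  expect_lt(abs(ld / sd(boot) - 1), 0.15)

  # estimated-PS efficiency: LD SE never above the fixed-weight sandwich
  set.seed(86)
  cmp <- replicate(50, {
    dd <- simulate_complete(sp, 500)
    pp <- fit_ps(dd$X, dd$z, sp$confounders)
    c(ld_se_iptw(dd$y, dd$z, pp$scores,
                 dd$X[, sp$confounders, drop = FALSE], "difference"),
      estimate_weighted(dd$y, dd$z, iptw_weights(pp$scores, dd$z),
                        "difference")$se)
  })
  expect_true(all(cmp[1, ] <= cmp[2, ]))
})

test_that("LD sandwich reduces to the two-sample SE in the degenerate case", {
  # no confounding and a non-prognostic covariate: estimating the propensity
  # score brings no information, so LD ~ two-sample SE of the mean difference
  sp <- make_scenario("S1")
  sp$alpha <- c(0, 0); sp$alpha0 <- 0; sp$gamma <- -5
  sp$beta <- c(-1, 0)
  set.seed(87)
  d <- simulate_complete(sp, 1e4)
  ps <- fit_ps(d$X, d$z, 2L)
  ld <- ld_se_iptw(d$y, d$z, ps$scores, d$X[, 2, drop = FALSE], "difference")
  two_sample <- sqrt(var(d$y[d$z == 1]) / sum(d$z == 1) +
                       var(d$y[d$z == 0]) / sum(d$z == 0))
  expect_lt(abs(ld / two_sample - 1), 0.1)
})

test_that("calipers are positive and scale as defined", {
  e <- plogis(c(-1, 1) / sqrt(2))  # logit-scale SD exactly 1
  cal <- compute_caliper(e, c(0L, 1L), "logit_sd")
  expect_equal(as.numeric(cal), 0.2, tolerance = 1e-12)
  expect_equal(attr(cal, "scale"), "logit")
  cal2 <- compute_caliper(e, c(0L, 1L), "logit_sd", width_multiplier = 0.4)
  expect_equal(as.numeric(cal2), 2 * as.numeric(cal), tolerance = 1e-12)

  set.seed(88)
  e <- runif(100, 0.2, 0.8)
  z <- rbinom(100, 1, e)
  caly <- compute_caliper(e, z, "youden")
  expect_gt(as.numeric(caly), 0)
  expect_equal(attr(caly, "scale"), "ps")
  expect_error(compute_caliper(rep(0.5, 10), rbinom(10, 1, 0.5)), "constant")
})

test_that("greedy matching pairs nearest available controls within caliper", {
  e <- c(0.30, 0.29, 0.50)
  z <- c(1L, 0L, 0L)
  set.seed(89)
  pairs <- greedy_match(e, z, 0.05, match_scale = "ps")
  expect_equal(nrow(pairs), 1L)
  expect_equal(unname(pairs[1, ]), c(1L, 2L))

  pairs0 <- greedy_match(c(0.30, 0.50), c(1L, 0L), 0.05, match_scale = "ps")
  expect_equal(nrow(pairs0), 0L)
  expect_error(greedy_match(e, z, 0), "positive")
})

test_that("matching output passes the brute-force validity checker", {
  set.seed(90)
  for (r in 1:100) {
    n <- 20
    e <- runif(n, 0.05, 0.95)
    z <- as.integer(rbinom(n, 1, 0.4))
    if (all(z == 1) || all(z == 0)) next
    cal <- 0.3
    pairs <- greedy_match(e, z, cal, match_scale = "logit")
    expect_true(validate_matching(pairs, e, z, cal, scale = "logit"))
    if (nrow(pairs) >= 2) {
      y <- rnorm(n)
      est <- estimate_matched(y, z, pairs, "difference")
      expect_identical(est$n_used %% 2L, 0L)
    }
  }
})

test_that("matched estimates equal the mean within-pair difference", {
  set.seed(91)
  n <- 60
  y <- rnorm(n)
  z <- rep(c(1L, 0L), n / 2)
  pairs <- cbind(exposed = which(z == 1)[1:20], control = which(z == 0)[1:20])
  est <- estimate_matched(y, z, pairs, "difference")
  expect_lt(abs(est$estimate - mean(y[pairs[, 1]] - y[pairs[, 2]])), 1e-8)
  expect_equal(est$n_used, 40L)

  # perfectly matched null data
  ynull <- rep(seq_len(20), 2)[order(rep(1:20, 2))]
  ynull <- numeric(n); ynull[pairs[, 1]] <- 1:20; ynull[pairs[, 2]] <- 1:20
  estn <- estimate_matched(ynull, z, pairs, "difference")
  expect_lt(abs(estn$estimate), 1e-10)
  expect_error(estimate_matched(y, z, pairs[0, , drop = FALSE]), "pairs")
})

test_that("stratification cuts deciles and is harmless without confounding", {
  set.seed(92)
  n <- 1000
  e <- runif(n)
  breaks <- unique(quantile(e, probs = seq(0, 1, 0.1)))
  counts <- table(cut(e, breaks, include.lowest = TRUE, right = TRUE))
  expect_true(all(abs(counts - n / 10) <= 1))

  set.seed(93)
  n <- 1e4
  e <- runif(n)
  z <- rbinom(n, 1, 0.5)
  y <- rnorm(n) + z
  est <- estimate_stratified(y, z, e)
  expect_lt(abs(est$estimate - (mean(y[z == 1]) - mean(y[z == 0]))), 1e-2)
  expect_gt(est$se, 0)
})

test_that("strata with one exposure arm are dropped with a warning", {
  set.seed(94)
  n <- 200
  e <- c(runif(n - 20, 0.3, 0.9), runif(20, 0.0, 0.02))
  z <- c(rbinom(n - 20, 1, 0.5), rep(0L, 20))  # lowest stratum: controls only
  y <- rnorm(n) + z
  expect_warning(est <- estimate_stratified(y, z, e), "single exposure arm")
  expect_lt(est$n_used, n)
})
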