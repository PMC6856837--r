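# Scenario construction, calibration and the generative model.

test_that("scenario table carries the design parameters", {
  s1 <- make_scenario("S1")
  expect_equal(s1$p, 2L)
  expect_equal(s1$beta, c(-1, 1))
  expect_equal(s1$alpha, c(0, log(2)))
  expect_equal(s1$confounders, 2L)

  s4 <- make_scenario("S4")
  expect_equal(s4$alpha, c(0, log(2), -log(2), log(2)))
  s5 <- make_scenario("S5")
  expect_equal(s5$alpha, c(0, log(1.65), log(1.65), log(1.65)))
  expect_equal(s5$beta, c(-1, 1, -1, -1))

  # S7/S8 reuse the S6 baseline
  s6 <- make_scenario("S6"); s7 <- make_scenario("S7"); s8 <- make_scenario("S8")
  expect_equal(s7$alpha, s6$alpha)
  expect_equal(s8$beta, s6$beta)
  expect_equal(s7$outcome_type, "binary")
  expect_equal(s8$missing_mechanism, "MNAR")
  expect_equal(s7$beta_z, log(2))

  expect_error(make_scenario("S9"), "unknown scenario")
  expect_error(make_scenario("S1", outcome_type = "binary"), "defined with")
  expect_error(make_scenario("S1", missing_rate_target = 1.2), "in \\(0, 1\\)")
})

test_that("covariates follow the scenario's correlation structure", {
  set.seed(41)
  X3 <- draw_covariates(make_scenario("S3"), 1e5)
  expect_lt(abs(cor(X3[, 2], X3[, 3]) - 0.5), 0.01)
  expect_lt(abs(cor(X3[, 3], X3[, 4]) - 0.5), 0.01)
  expect_lt(abs(cor(X3[, 1], X3[, 2])), 0.01)

  X2 <- draw_covariates(make_scenario("S2"), 1e5)
  expect_lt(abs(cor(X2[, 2], X2[, 3])), 0.01)
  expect_true(all(abs(colMeans(X2)) < 0.02))
  expect_true(all(abs(apply(X2, 2, var) - 1) < 0.03))
  expect_error(draw_covariates(make_scenario("S1"), 0), "positive")
})

test_that("exposure intercept calibration hits the prevalence target", {
  sp <- make_scenario("S1")
  set.seed(42)
  a0_half <- calibrate_exposure_intercept(sp, n_mc = 1e6)
  sp$alpha0 <- a0_half
  set.seed(43)
  X <- draw_covariates(sp, 1e6)
  expect_lt(abs(mean(draw_exposure(sp, X)) - 0.5), 0.002)

  sp10 <- make_scenario("S1", exposure_prevalence_target = 0.1)
  set.seed(44)
  a0_low <- calibrate_exposure_intercept(sp10, n_mc = 1e6)
  expect_lt(a0_low, 0)
  sp10$alpha0 <- a0_low
  set.seed(45)
  X <- draw_covariates(sp10, 1e6)
  expect_lt(abs(mean(draw_exposure(sp10, X)) - 0.1), 0.002)

  # alpha = 0 with a symmetric target needs no shift
  sp0 <- sp
  sp0$alpha <- c(0, 0)
  set.seed(46)
  expect_lt(abs(calibrate_exposure_intercept(sp0, n_mc = 1e6)), 0.01)
})

test_that("exposure draws follow the logistic assignment model", {
  sp <- make_scenario("S1")
  expect_error(draw_exposure(sp, matrix(0, 5, 2)), "not calibrated")
  sp$alpha0 <- -Inf
  expect_equal(draw_exposure(sp, matrix(0, 50, 2)), rep(0L, 50))

  sp$alpha0 <- 0
  set.seed(47)
  X <- draw_covariates(sp, 1e5)
  z <- draw_exposure(sp, X)
  refit <- glm(z ~ X[, 2], family = binomial)
  expect_lt(abs(unname(coef(refit)[2]) - log(2)), 0.05)
})

test_that("continuous outcomes follow the linear model with effect 2", {
  sp <- make_scenario("S1")
  expect_equal(simulate_continuous_outcome(sp, matrix(0, 3, 2), rep(1L, 3),
                                           noise_sd = 0),
               rep(sp$beta0 + 2, 3))
  expect_equal(simulate_continuous_outcome(sp, matrix(0, 3, 2), rep(0L, 3),
                                           noise_sd = 0),
               rep(sp$beta0, 3))
  expect_error(simulate_continuous_outcome(sp, matrix(0, 3, 3), rep(0L, 3)),
               "dimension mismatch")

  sp <- cached_spec("S1")
  set.seed(48)
  d <- simulate_complete(sp, 1e5)
  refit <- lm(d$y ~ d$X[, 1] + d$X[, 2] + d$z)
  expect_lt(abs(unname(coef(refit)["d$z"]) - 2), 0.02)
})

test_that("binary outcomes generate consistent potential outcomes", {
  sp <- make_scenario("S7")
  sp$alpha0 <- 0
  sp$beta0 <- -1e6  # linear predictor -> -Inf
  out <- simulate_binary_outcome(sp, matrix(0, 20, 4), rep(1L, 20))
  expect_equal(out$y_pot0, rep(0L, 20))
  expect_equal(out$y_pot1, rep(0L, 20))

  sp$beta0 <- 0
  set.seed(49)
  out <- simulate_binary_outcome(sp, matrix(0, 1e5, 4), rep(1L, 1e5))
  expect_lt(abs(mean(out$y_pot1) - 2 / 3), 0.01)
  expect_lt(abs(mean(out$y_pot0) - 1 / 2), 0.01)

  sp7 <- cached_spec("S7")
  set.seed(50)
  d <- simulate_complete(sp7, 1e5)
  expect_lt(abs(mean(d$y) - 0.5), 0.01)  # calibrated event rate
  expect_identical(d$y, ifelse(d$z == 1L, d$y_pot1, d$y_pot0))  # consistency
})

test_that("true marginal risk ratio matches closed forms and is stable", {
  # no covariate effects, intercept 0: p1 = expit(ln 2) = 2/3, p0 = 1/2
  sp <- make_scenario("S7")
  sp$alpha0 <- 0; sp$beta0 <- 0
  sp$beta <- rep(0, 4)
  set.seed(51)
  expect_lt(abs(true_marginal_rr(sp, 1e6) - 4 / 3), 0.005)

  sp$beta_z <- 0  # null exposure effect
  set.seed(52)
  expect_lt(abs(true_marginal_rr(sp, 1e6) - 1), 0.005)

  sp7 <- cached_spec("S7")
  set.seed(53); rr_a <- true_marginal_rr(sp7, 1e6)
  set.seed(54); rr_b <- true_marginal_rr(sp7, 1e6)
  expect_gt(rr_a, 1)          # attenuated marginal RR:
  expect_lt(rr_a, 2)          # strictly between 1 and the conditional OR 2
  expect_lt(abs(rr_a - rr_b), 0.005)
})

test_that("missingness calibration hits the target rate for MAR and MNAR", {
  sp <- cached_spec("S1")
  set.seed(55)
  d <- simulate_complete(sp, 1e6)
  obs <- impose_missingness(d, sp)
  expect_lt(abs(mean(obs$mask[, 2]) - 0.25), 0.005)

  sp8 <- cached_spec("S8", rate = 0.5)
  set.seed(56)
  d8 <- simulate_complete(sp8, 2e5)
  obs8 <- impose_missingness(d8, sp8)
  expect_lt(abs(mean(obs8$mask[, sp8$confounders]) - 0.5), 0.005)
})

test_that("missingness touches confounders only and follows its model", {
  sp <- cached_spec("S1")
  set.seed(57)
  obs <- simulate_observed(sp, 1e5)
  expect_true(all(obs$mask[, -sp$confounders] == 0L))  # non-confounders intact
  expect_false(anyNA(obs$z) || anyNA(obs$y))

  # logistic refit of the MAR mechanism recovers its slopes
  mis <- obs$mask[, 2]
  refit <- glm(mis ~ obs$X[, 1] + obs$y, family = binomial)
  expect_lt(abs(unname(coef(refit)[2]) - log(1.25)), 0.03)
  refit2 <- glm(mis ~ obs$X[, 1] + obs$y + obs$X[, 2], family = binomial)
  expect_lt(abs(unname(coef(refit2)[4])), 0.03)  # MAR: no dependence on x2

  sp_off <- sp
  sp_off$gamma <- -Inf
  set.seed(58)
  d <- simulate_complete(sp_off, 1000)
  obs0 <- impose_missingness(d, sp_off)
  expect_true(all(obs0$mask == 0L))
  expect_identical(obs0$X_obs, d$X)
})

test_that("confounding exists and the true-model propensity removes it", {
  sp <- cached_spec("S1")
  set.seed(59)
  iptw <- crude <- numeric(1000)
  for (k in seq_len(1000)) {
    d <- simulate_complete(sp, 1000)
    ps <- fit_ps(d$X, d$z, sp$confounders)
    iptw[k] <- estimate_weighted(d$y, d$z, iptw_weights(ps$scores, d$z),
                                 "difference")$estimate
    crude[k] <- unname(coef(lm.fit(cbind(1, d$z), d$y))[2])
  }
  expect_lt(abs(mean(iptw) - 2), 0.03)  # complete-data IPTW is unbiased
  expect_gt(mean(crude) - 2, 0.3)       # crude estimate is confounded upward
})

test_that("observed datasets export to CSV with empty missing fields", {
  sp <- cached_spec("S1")
  set.seed(60)
  obs <- simulate_observed(sp, 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed_csv(obs, path)
  back <- read.csv(path)
  expect_equal(names(back), c("x1", "x2", "z", "y"))
  expect_equal(is.na(back$x2), obs$mask[, 2] == 1L)
  expect_equal(back$y, obs$y, tolerance = 1e-12)
})
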