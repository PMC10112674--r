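test_that("per-observation log-likelihood matches a direct normal-CDF oracle", {
  # worked values
  expect_identical(obs_loglik(-Inf, Inf, 0.3, -1), 0)
  expect_equal(obs_loglik(0.5, Inf, 0.5, log(2)), log(0.5))
  expect_equal(obs_loglik(-1.96, 1.96, 0, 0), log(pnorm(1.96) - pnorm(-1.96)))
  expect_equal(obs_loglik(-1.96, 1.96, 0, 0), -0.0512889, tolerance = 1e-6)

  # 1000 random (mu, sigma, interval) triples against the naive formula
  set.seed(31)
  for (i in 1:1000) {
    mu <- runif(1, -1, 1)
    sigma <- runif(1, 0.05, 1.5)
    a <- sort(runif(2, mu - 4 * sigma, mu + 4 * sigma))
    kind <- sample(3, 1)
    l <- if (kind == 1) -Inf else a[1]
    u <- if (kind == 2) Inf else a[2]
    naive <- log(pnorm((u - mu) / sigma) - pnorm((l - mu) / sigma))
    expect_equal(obs_loglik(l, u, mu, log(sigma)), naive, tolerance = 1e-10)
  }
})

test_that("log-likelihood stays finite for extreme standardized bounds", {
  # both bounds 40+ sigma out in the same tail: naive difference underflows
  ll <- obs_loglik(40, 41, 0, 0)
  expect_true(is.finite(ll))
  expect_lt(ll, -700)
  ll2 <- obs_loglik(-41, -40, 0, 0)
  expect_equal(ll, ll2, tolerance = 1e-8)
  expect_error(obs_loglik(0.2, 0.1, 0, 0), "lower < upper")
})

test_that("analytic score matches finite differences on random points", {
  set.seed(17)
  X <- cbind(1, rbinom(40, 1, 0.5), rnorm(40))
  for (rep in 1:100) {
    beta <- runif(3, -0.3, 0.3)
    lns <- runif(1, -3, 0)
    w <- rnorm(40, drop(X %*% beta), exp(lns))
    resp <- simulate_responses(w)
    iv <- map_to_interval(resp$response1, resp$response2, resp$followup_frac)
    th <- c(beta, lns)
    f <- function(t) sum(obs_loglik(iv$lower, iv$upper, drop(X %*% t[1:3]), t[4]))
    g_analytic <- colSums(equiwtp:::.score_matrix(iv$lower, iv$upper, X, beta, lns))
    h <- 1e-6
    g_fd <- vapply(1:4, function(j) {
      e <- replace(numeric(4), j, h)
      (f(th + e) - f(th - e)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g_analytic), g_fd, tolerance = 1e-5)
  }
})

test_that("analytic Hessian matches finite differences of the score", {
  set.seed(23)
  X <- cbind(1, rnorm(60))
  beta <- c(0.15, 0.05); lns <- -2
  w <- rnorm(60, drop(X %*% beta), exp(lns))
  resp <- simulate_responses(w)
  iv <- map_to_interval(resp$response1, resp$response2, resp$followup_frac)
  H <- equiwtp:::.loglik_hessian(iv$lower, iv$upper, X, beta, lns)
  th <- c(beta, lns)
  g <- function(t) colSums(equiwtp:::.score_matrix(iv$lower, iv$upper, X, t[1:2], t[3]))
  h <- 1e-6
  H_fd <- sapply(1:3, function(j) {
    e <- replace(numeric(3), j, h)
    (g(th + e) - g(th - e)) / (2 * h)
  })
  expect_equal(H, unname((H_fd + t(H_fd)) / 2), tolerance = 1e-4)
})

test_that("intercept-only fit matches the brute-force grid oracle", {
  iv <- sim_intercept_data(30, mu = 0.15, sigma = 0.06, seed = 4)
  fit <- fit_interval_reg(iv$lower, iv$upper, matrix(1, 30, 1))
  expect_true(fit$converged)
  step <- 0.002
  oracle <- grid_fit_intercept(iv$lower, iv$upper,
                               beta_range = c(0.05, 0.30),
                               lnsig_range = c(-4.5, -1.5), step = step)
  expect_lt(abs(unname(fit$beta[1]) - oracle$beta0), 2 * step)
  expect_lt(abs(fit$ln_sigma - oracle$ln_sigma), 2 * step)
  expect_gte(fit$loglik, oracle$loglik - 1e-8)
})

test_that("fit agrees with survreg's interval-censored gaussian ML", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 400
  X <- cbind(1, rbinom(n, 1, 0.4))
  colnames(X) <- c("(Intercept)", "x1")
  w <- rnorm(n, 0.12 + 0.06 * X[, 2], 0.08)
  resp <- simulate_responses(w)
  iv <- map_to_interval(resp$response1, resp$response2, resp$followup_frac)
  fit <- fit_interval_reg(iv$lower, iv$upper, X)

  time1 <- ifelse(is.finite(iv$lower), iv$lower, NA)
  time2 <- ifelse(is.finite(iv$upper), iv$upper, NA)
  sr <- survival::survreg(
    survival::Surv(time1, time2, type = "interval2") ~ X[, 2],
    dist = "gaussian"
  )
  expect_equal(unname(fit$beta), unname(coef(sr)), tolerance = 1e-5)
  expect_equal(fit$ln_sigma, log(sr$scale), tolerance = 1e-5)
  expect_equal(fit$loglik, sr$loglik[2], tolerance = 1e-6)
})

test_that("simulated truth is recovered within 3 robust SEs (intercept-only)", {
  iv <- sim_intercept_data(2000, mu = 0.20, sigma = 0.05, seed = 8)
  fit <- fit_interval_reg(iv$lower, iv$upper, matrix(1, 2000, 1))
  se <- sqrt(diag(fit$vcov_robust))
  expect_lt(abs(unname(fit$beta[1]) - 0.20), 3 * se[1])
  expect_lt(abs(fit$sigma - 0.05) / 0.05, 0.10)
})

test_that("identification and rank failures produce informative errors", {
  expect_error(fit_interval_reg(rep(-Inf, 40), rep(Inf, 40), matrix(1, 40, 1)),
               "unidentified")
  iv <- sim_intercept_data(40, 0.15, 0.05, seed = 2)
  X <- cbind(a = rep(1, 40), b = rep(1, 40) * 2)
  expect_error(fit_interval_reg(iv$lower, iv$upper, X), "collinear")
  expect_error(fit_interval_reg(iv$lower[1:3], iv$upper[1:3],
                                cbind(1, rnorm(3), rnorm(3))),
               "too few")
  expect_error(fit_interval_reg(c(0.1, NA), c(0.2, 0.3), matrix(1, 2, 1)),
               "complete")
})

test_that("tightening an interval never increases its log-likelihood", {
  set.seed(12)
  for (i in 1:200) {
    mu <- runif(1, -0.5, 0.5); lns <- runif(1, -3, 0)
    l <- runif(1, -1, 0.5); u <- l + runif(1, 0.01, 1)
    shrink <- runif(2, 0, 0.45) * (u - l)
    expect_lte(obs_loglik(l + shrink[1], u - shrink[2], mu, lns),
               obs_loglik(l, u, mu, lns) + 1e-12)
  }
})

test_that("sandwich covariance is symmetric PSD and near model-based SEs", {
  iv <- sim_intercept_data(4000, 0.15, 0.07, seed = 19)
  set.seed(19)
  X <- cbind(1, rbinom(4000, 1, 0.5))
  fit <- fit_interval_reg(iv$lower, iv$upper, X)
  V <- fit$vcov_robust
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  # correctly specified homoskedastic model: robust and model SEs agree
  se_r <- sqrt(diag(fit$vcov_robust))
  se_m <- sqrt(diag(fit$vcov_model))
  expect_true(all(abs(se_r / se_m - 1) < 0.15))
  # recomputation path matches what the fit stored
  expect_equal(robust_covariance(fit), V, tolerance = 1e-8)
  # small-sample factor scales the whole matrix
  k <- fit$k + 1
  expect_equal(robust_covariance(fit, dfc = TRUE),
               V * fit$n / (fit$n - k), tolerance = 1e-8)
})

test_that("Wald statistic is the squared z for a single slope", {
  V <- diag(c(0.5, 0.01, 0.3))
  dimnames(V) <- rep(list(c("(Intercept)", "x", "ln_sigma")), 2)
  fit <- wtp_fit_from_coef(c("(Intercept)" = 0.1, x = 0.2), ln_sigma = -2,
                           vcov_robust = V)
  wt <- wald_test(fit)
  expect_equal(wt$chi2, 4) # z = 0.2 / 0.1 = 2
  expect_equal(wt$df, 1)
  expect_equal(wt$p, pchisq(4, 1, lower.tail = FALSE))
})

test_that("Wald df equals the slope count of each group's model layout", {
  expect_equal(length(model_covariates("owner")), 13)
  expect_equal(length(model_covariates("boarder")), 15)
  expect_equal(length(model_covariates("leaser")), 13)
  ds <- end_to_end_dataset(synthetic_config(seed = 77, overrides = list(
    owner = list(n = 400), boarder = list(n = 0), leaser = list(n = 0)
  )))
  fit <- estimate_group(ds$records, "owner")
  expect_equal(fit$wald_df, 13)
})

test_that("sequence probabilities telescope to one and match the normal CDF", {
  p <- sequence_probabilities(mu = 0.155, sigma = 0.05, c2y = 0.15, c2n = 0.05)
  expect_equal(unname(p["yes_yes"]), 1 - pnorm(-0.1), tolerance = 1e-12)
  expect_equal(unname(p["yes_yes"]), 0.5398, tolerance = 1e-4)
  set.seed(3)
  for (i in 1:50) {
    p <- sequence_probabilities(runif(1, -0.3, 0.5), runif(1, 0.01, 0.3),
                                c2y = sample(11:20, 1) / 100,
                                c2n = sample(1:9, 1) / 100)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(sequence_probabilities(0.1, 0.05, c2y = 0.08, c2n = 0.05),
               "c2n < c1 < c2y")
})
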