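# Interval-censored Gaussian regression by maximum likelihood.
#
# The latent willingness to pay (as a fraction of current care cost) is
# modeled as WTP_i = x_i'beta + eps_i with iid normal errors of scale sigma.
# Each observation contributes log[Phi((u_i - mu_i)/sigma) -
# Phi((l_i - mu_i)/sigma)], the probability that a normal variate falls in
# the censored interval [l_i, u_i) produced by the bid design; left/right
# censoring are the one-sided special cases.  The model is parameterized in
# (beta, log sigma) so the scale stays positive on every iterate, maximized
# by Newton-Raphson with analytic score and Hessian, and reported with a
# sandwich (robust) covariance.

#' Per-observation interval log-likelihood
#'
#' Log-probability that a Normal(`mu`, `sigma^2`) variate lies in
#' `[lower, upper)`, computed with tail-stable log-CDF differences so that
#' extreme standardized bounds do not underflow to `-Inf` spuriously.
#' `lower = -Inf` gives the left-censored term `log Phi((u-mu)/sigma)`;
#' `upper = +Inf` the right-censored `log(1 - Phi((l-mu)/sigma))`; a doubly
#' unbounded interval contributes exactly 0.
#'
#' @param lower,upper interval bounds (may be `-Inf` / `+Inf`); vectors.
#' @param mu mean(s) `x'beta`.
#' @param ln_sigma log of the error scale (scalar or vector).
#' @return numeric vector of log-likelihood contributions, each `<= 0`.
#' @examples
#' obs_loglik(-Inf, Inf, 0, 0)        # 0
#' obs_loglik(0, Inf, 0, 0)           # log(0.5)
#' obs_loglik(-1.96, 1.96, 0, 0)      # log(0.9500042)
#' @export
obs_loglik <- function(lower, upper, mu, ln_sigma) {
  n <- max(length(lower), length(upper), length(mu), length(ln_sigma))
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  mu <- rep_len(mu, n); sigma <- exp(rep_len(ln_sigma, n))
  if (any(lower >= upper)) stop("every interval must satisfy lower < upper")
  zl <- ifelse(is.infinite(lower), -Inf, (lower - mu) / sigma)
  zu <- ifelse(is.infinite(upper), Inf, (upper - mu) / sigma)
  log_pnorm_diff(zl, zu)
}

# standardized bounds and the density/probability ratios that drive the
# score and Hessian: RA = phi(zl)/P, RB = phi(zu)/P (0 at infinite bounds)
.interval_ratios <- function(lower, upper, mu, sigma) {
  zl <- ifelse(is.infinite(lower), -Inf, (lower - mu) / sigma)
  zu <- ifelse(is.infinite(upper), Inf, (upper - mu) / sigma)
  lp <- log_pnorm_diff(zl, zu)
  ra <- ifelse(is.finite(zl), exp(stats::dnorm(zl, log = TRUE) - lp), 0)
  rb <- ifelse(is.finite(zu), exp(stats::dnorm(zu, log = TRUE) - lp), 0)
  zra <- ifelse(is.finite(zl), zl * ra, 0)   # zl * phi(zl)/P, 0 in the limit
  zrb <- ifelse(is.finite(zu), zu * rb, 0)
  list(zl = zl, zu = zu, lp = lp, ra = ra, rb = rb, zra = zra, zrb = zrb)
}

# n x (k+1) matrix of per-observation scores d ll_i / d(beta, ln_sigma)
.score_matrix <- function(lower, upper, X, beta, ln_sigma) {
  sigma <- exp(ln_sigma)
  mu <- drop(X %*% beta)
  r <- .interval_ratios(lower, upper, mu, sigma)
  g_mu <- (r$ra - r$rb) / sigma
  g_t <- r$zra - r$zrb
  cbind(X * g_mu, ln_sigma = g_t)
}

# analytic Hessian of the total log-likelihood in (beta, ln_sigma)
.loglik_hessian <- function(lower, upper, X, beta, ln_sigma) {
  sigma <- exp(ln_sigma)
  mu <- drop(X %*% beta)
  r <- .interval_ratios(lower, upper, mu, sigma)
  g_mu <- (r$ra - r$rb) / sigma
  g_t <- r$zra - r$zrb
  z2ra <- ifelse(is.finite(r$zl), r$zl^2 * r$ra, 0)
  z2rb <- ifelse(is.finite(r$zu), r$zu^2 * r$rb, 0)
  z3ra <- ifelse(is.finite(r$zl), r$zl^3 * r$ra, 0)
  z3rb <- ifelse(is.finite(r$zu), r$zu^3 * r$rb, 0)
  h_mumu <- (r$zra - r$zrb) / sigma^2 - g_mu^2
  h_mut <- (z2ra - z2rb) / sigma - g_mu * g_t - g_mu
  h_tt <- (z3ra - r$zra) - (z3rb - r$zrb) - g_t^2
  k <- ncol(X)
  H <- matrix(0, k + 1, k + 1)
  H[1:k, 1:k] <- crossprod(X, X * h_mumu)
  H[1:k, k + 1] <- H[k + 1, 1:k] <- colSums(X * h_mut)
  H[k + 1, k + 1] <- sum(h_tt)
  H
}

#' Fit an interval regression by maximum likelihood
#'
#' Maximizes the interval-censored normal log-likelihood over
#' `(beta, log sigma)` by Newton-Raphson with analytic score and Hessian and
#' step-halving, starting from an OLS fit to interval midpoints (censored
#' observations are imputed at the finite bound plus/minus 0.05 for the
#' initializer only).  Covariates are standardized internally for numerical
#' conditioning and estimates mapped back to the original scale.
#'
#' @param lower,upper numeric vectors of interval bounds in fraction-of-cost
#'   units (`-Inf`/`+Inf` allowed); at least one bound must be finite
#'   somewhere in the data or the model is unidentified.
#' @param X design matrix including an intercept column, or a data.frame of
#'   covariates (an intercept is prepended if no constant column is found).
#' @param control list of optimizer settings: `gtol` (max-abs gradient in the
#'   standardized parameterization, default `1e-8`), `maxit` (default 200),
#'   `dfc` (logical; apply the `n/(n-k)` small-sample factor to the sandwich
#'   covariance, default `FALSE`).
#' @return an object of class `"wtp_fit"`: a list with `beta` (named vector),
#'   `ln_sigma`, `sigma`, `loglik`, `vcov_robust` (sandwich covariance of
#'   `(beta, ln_sigma)`), `vcov_model` (inverse observed information),
#'   `wald_chi2`, `wald_df`, `wald_p`, `n`, `converged`, `iterations`,
#'   `xbar` (covariate means of the estimation sample), and the data it was
#'   fit to.
#' @seealso [wald_test()], [robust_covariance()], [wtp_at_means()]
#' @examples
#' set.seed(42)
#' w <- rnorm(300, 0.15, 0.05)
#' r1 <- ifelse(w >= 0.10, "yes", "no")
#' f2 <- draw_followup(r1)
#' r2 <- ifelse(r1 == "yes", ifelse(w >= f2, "yes", "no"),
#'                           ifelse(w >= f2, "yes", "no"))
#' iv <- map_to_interval(r1, r2, f2)
#' fit <- fit_interval_reg(iv$lower, iv$upper, X = matrix(1, 300, 1))
#' coef(fit)
#' @export
fit_interval_reg <- function(lower, upper, X, control = list()) {
  ctl <- utils::modifyList(list(gtol = 1e-8, maxit = 200L, dfc = FALSE), control)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(length(lower) == n, length(upper) == n)
  if (anyNA(lower) || anyNA(upper) || anyNA(X)) {
    stop("estimation data must be complete; apply listwise_filter() first")
  }
  if (any(lower >= upper)) stop("every interval must satisfy lower < upper")
  if (!any(is.finite(lower) | is.finite(upper))) {
    stop("model unidentified: no interval has a finite endpoint")
  }
  # ensure an intercept column and column names
  has_const <- apply(X, 2, function(col) all(col == col[1]) && col[1] != 0)
  if (!any(has_const)) {
    X <- cbind("(Intercept)" = 1, X)
  } else if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cn <- colnames(X)
  ones <- which(apply(X, 2, function(col) all(col == 1)))
  if (length(ones)) cn[ones[1]] <- "(Intercept)"
  colnames(X) <- cn
  k <- ncol(X)
  if (n <= k + 1) stop("too few observations (n = ", n, ") for ", k + 1, " parameters")
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- cn[qrX$pivot[(qrX$rank + 1):k]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  # standardize non-constant columns for conditioning
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  Xs <- sweep(X, 2, s, "/")

  # initializer: OLS on midpoints with censored bounds nudged inward
  mid <- ifelse(is.finite(lower) & is.finite(upper), (lower + upper) / 2,
    ifelse(is.finite(lower), lower + 0.05, upper - 0.05)
  )
  beta_s <- qr.coef(qr(Xs), mid)
  resid <- mid - drop(Xs %*% beta_s)
  t0 <- log(max(stats::sd(resid), 1e-3))
  theta <- c(beta_s, t0)

  ll_fun <- function(th) {
    sum(obs_loglik(lower, upper, drop(Xs %*% th[1:k]), th[k + 1]))
  }
  gr_fun <- function(th) {
    colSums(.score_matrix(lower, upper, Xs, th[1:k], th[k + 1]))
  }

  ll <- ll_fun(theta)
  if (!is.finite(ll)) stop("initializer produced a non-finite likelihood")
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(ctl$maxit)) {
    g <- gr_fun(theta)
    if (max(abs(g)) <= ctl$gtol) { converged <- TRUE; break }
    H <- .loglik_hessian(lower, upper, Xs, theta[1:k], theta[k + 1])
    info <- -H
    step <- tryCatch(solve(info, g), error = function(e) NULL)
    ridge <- 1e-8 * max(abs(diag(info)), 1)
    while (is.null(step) || any(!is.finite(step))) {
      info <- info + diag(ridge, k + 1)
      ridge <- ridge * 10
      step <- tryCatch(solve(info, g), error = function(e) NULL)
      if (ridge > 1e12) stop("singular Hessian; model may be unidentified")
    }
    # step-halving line search on the ascent direction
    lam <- 1
    repeat {
      cand <- theta + lam * step
      ll_new <- ll_fun(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
      lam <- lam / 2
      if (lam < 1e-12) break
    }
    if (lam < 1e-12) break
    theta <- theta + lam * step
    ll <- ll_fun(theta)
  }
  g <- gr_fun(theta)
  converged <- max(abs(g)) <= ctl$gtol
  if (!converged) {
    warning("interval regression did not converge (max |score| = ",
            format(max(abs(g)), digits = 3), ")")
  }

  # map back to the original covariate scale
  M <- diag(c(1 / s, 1), k + 1)
  beta <- theta[1:k] / s
  names(beta) <- cn
  ln_sigma <- unname(theta[k + 1])

  Hs <- .loglik_hessian(lower, upper, Xs, theta[1:k], ln_sigma)
  info_s <- -Hs
  vcov_model_s <- tryCatch(solve(info_s), error = function(e) {
    stop("singular observed information; cannot compute covariance")
  })
  S_s <- .score_matrix(lower, upper, Xs, theta[1:k], ln_sigma)
  meat_s <- crossprod(S_s)
  vcov_rob_s <- vcov_model_s %*% meat_s %*% vcov_model_s
  if (isTRUE(ctl$dfc)) vcov_rob_s <- vcov_rob_s * n / (n - (k + 1))
  vcov_model <- M %*% vcov_model_s %*% M
  vcov_rob <- M %*% vcov_rob_s %*% M
  vcov_rob <- (vcov_rob + t(vcov_rob)) / 2
  vcov_model <- (vcov_model + t(vcov_model)) / 2
  pnames <- c(cn, "ln_sigma")
  dimnames(vcov_rob) <- dimnames(vcov_model) <- list(pnames, pnames)

  fit <- structure(list(
    beta = beta, ln_sigma = ln_sigma, sigma = exp(ln_sigma),
    loglik = ll, n = n, k = k,
    vcov_robust = vcov_rob, vcov_model = vcov_model,
    converged = converged, iterations = iter,
    xbar = colMeans(X),
    data = list(lower = lower, upper = upper, X = X),
    control = ctl
  ), class = "wtp_fit")
  wt <- wald_test(fit)
  fit$wald_chi2 <- wt$chi2; fit$wald_df <- wt$df; fit$wald_p <- wt$p
  fit
}

#' Construct a fit object from published coefficients
#'
#' Builds a minimal `"wtp_fit"` carrying a coefficient vector (and optionally
#' a scale and covariance) taken from a reported results table, so that
#' downstream reporting tools such as [marginal_effect()] and
#' [wtp_at_means()] can be applied to published models whose raw data are
#' unavailable.
#'
#' @param beta named numeric vector of coefficients in fraction-of-cost
#'   units (the per-dollar cost coefficient is fraction per USD).
#' @param ln_sigma log error scale (default `NA`).
#' @param vcov_robust optional covariance matrix of `(beta, ln_sigma)`.
#' @param n optional sample size.
#' @return a `"wtp_fit"` object with `converged = NA`.
#' @examples
#' fit <- wtp_fit_from_coef(c(current_cost = -1e-4))
#' marginal_effect(fit, "current_cost", delta = 100)  # -0.01
#' @export
wtp_fit_from_coef <- function(beta, ln_sigma = NA_real_, vcov_robust = NULL,
                              n = NA_integer_) {
  stopifnot(is.numeric(beta), !is.null(names(beta)))
  structure(list(
    beta = beta, ln_sigma = ln_sigma, sigma = exp(ln_sigma),
    loglik = NA_real_, n = n, k = length(beta),
    vcov_robust = vcov_robust, vcov_model = NULL,
    converged = NA, iterations = 0L, xbar = NULL, data = NULL,
    control = list()
  ), class = "wtp_fit")
}

#' Sandwich (robust) covariance of an interval-regression fit
#'
#' Recomputes the heteroskedasticity-robust covariance
#' `H^-1 (sum s_i s_i') H^-1` at the fitted optimum, where `s_i` is the
#' per-observation score of the interval log-likelihood and `H` the observed
#' information (negative Hessian of the total log-likelihood).
#'
#' @param fit a converged [fit_interval_reg()] result.
#' @param dfc apply the `n/(n-k)` small-sample scaling (for cross-checks
#'   against implementations that do), default `FALSE`.
#' @return symmetric covariance matrix for `(beta, ln_sigma)`.
#' @export
robust_covariance <- function(fit, dfc = FALSE) {
  stopifnot(inherits(fit, "wtp_fit"))
  if (is.null(fit$data)) stop("fit carries no data; refit with fit_interval_reg()")
  d <- fit$data
  H <- .loglik_hessian(d$lower, d$upper, d$X, fit$beta, fit$ln_sigma)
  info <- -H
  bread <- solve(info)
  S <- .score_matrix(d$lower, d$upper, d$X, fit$beta, fit$ln_sigma)
  V <- bread %*% crossprod(S) %*% bread
  if (dfc) V <- V * fit$n / (fit$n - (fit$k + 1))
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(fit$vcov_robust)
  V
}

#' Wald test that all slope coefficients are zero
#'
#' Joint chi-square test of the non-intercept regression coefficients using
#' the robust covariance block; the intercept and `ln_sigma` are not tested.
#'
#' @param fit a [fit_interval_reg()] result.
#' @return list with `chi2`, `df` (number of slopes) and `p`.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "wtp_fit"))
  slopes <- setdiff(names(fit$beta), "(Intercept)")
  if (length(slopes) == 0) return(list(chi2 = 0, df = 0L, p = NA_real_))
  b <- fit$beta[slopes]
  V <- fit$vcov_robust[slopes, slopes, drop = FALSE]
  chi2 <- drop(t(b) %*% solve(V, b))
  df <- length(slopes)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Closed-form response-sequence probabilities
#'
#' Probability of each double-bounded response sequence implied by the latent
#' normal WTP model and a bid schedule: with `mu = x'beta`,
#' `P(no,no) = Phi((c2n-mu)/sigma)`,
#' `P(no,yes) = Phi((c1-mu)/sigma) - Phi((c2n-mu)/sigma)`,
#' `P(yes,no) = Phi((c2y-mu)/sigma) - Phi((c1-mu)/sigma)`,
#' `P(yes,yes) = 1 - Phi((c2y-mu)/sigma)`.
#' Used by the simulator and for goodness-of-fit checks.
#'
#' @param mu latent mean WTP fraction(s).
#' @param sigma error scale, `> 0`.
#' @param c2y,c2n the realized follow-up fractions; must satisfy
#'   `c2n < c1 < c2y`.
#' @param c1 first bid fraction (default 0.10).
#' @return named numeric vector (or matrix, one row per `mu`) with entries
#'   `yes_yes`, `yes_no`, `no_yes`, `no_no` summing to 1.
#' @export
sequence_probabilities <- function(mu, sigma, c2y, c2n, c1 = bid_schedule()$c1) {
  stopifnot(sigma > 0)
  if (!(all(c2n < c1) && all(c1 < c2y))) stop("bid schedule must satisfy c2n < c1 < c2y")
  p_nn <- stats::pnorm((c2n - mu) / sigma)
  p_c1 <- stats::pnorm((c1 - mu) / sigma)
  p_c2y <- stats::pnorm((c2y - mu) / sigma)
  out <- cbind(
    yes_yes = 1 - p_c2y,
    yes_no = p_c2y - p_c1,
    no_yes = p_c1 - p_nn,
    no_no = p_nn
  )
  if (length(mu) == 1 && length(c2y) == 1 && length(c2n) == 1) drop(out) else out
}

#' @export
coef.wtp_fit <- function(object, ...) object$beta

#' @export
vcov.wtp_fit <- function(object, ...) object$vcov_robust

#' @export
logLik.wtp_fit <- function(object, ...) {
  structure(object$loglik, df = object$k + 1, nobs = object$n, class = "logLik")
}

#' @export
print.wtp_fit <- function(x, digits = 4, ...) {
  cat("Interval-censored normal WTP regression\n")
  if (!is.null(x$data)) {
    cat(sprintf("n = %d, logLik = %.3f, converged = %s (%d iterations)\n",
                x$n, x$loglik, x$converged, x$iterations))
  }
  se <- if (!is.null(x$vcov_robust)) {
    sqrt(diag(x$vcov_robust))[seq_along(x$beta)]
  } else rep(NA_real_, length(x$beta))
  z <- x$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(
    Coefficient = round(x$beta, digits), `Robust SE` = round(se, digits),
    z = round(z, 2), p = signif(p, 3), ` ` = p_stars(p),
    check.names = FALSE
  )
  print(tab)
  if (is.finite(x$ln_sigma)) {
    cat(sprintf("Ln(Sigma) = %.4f  (sigma = %.4f)\n", x$ln_sigma, x$sigma))
  }
  if (!is.null(x$wald_chi2)) {
    cat(sprintf("Wald chi2(%d) = %.2f, p = %.4g\n", x$wald_df, x$wald_chi2, x$wald_p))
  }
  invisible(x)
}
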