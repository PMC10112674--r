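# Headline quantities from a fitted model: mean WTP as the linear
# prediction at covariate means with delta-method uncertainty, marginal
# effects, and results-table formatting.

#' Mean WTP as the linear prediction at covariate means
#'
#' The headline estimate: `xbar' beta_hat`, with the covariate means taken
#' over the estimation sample (after listwise deletion) and treated as fixed
#' constants, so the delta-method standard error is
#' `sqrt(xbar' V xbar)` with `V` the robust covariance block of `beta`.
#' Optionally the sampling variance of the means themselves can be added for
#' sensitivity (`mean_variance = TRUE`).
#'
#' @param fit a converged [fit_interval_reg()] result.
#' @param xbar optional covariate-mean vector (defaults to the fit's
#'   estimation-sample means, intercept included).
#' @param mean_variance add `beta' Cov(xbar) beta` to the variance,
#'   treating the means as estimated; default `FALSE`.
#' @return list of class `"wtp_estimate"`: `point` (fraction of current
#'   cost), `se`, `z`, `p`, `covariate_means`, and `dollars_per_month` (the
#'   point estimate scaled by the mean current cost when that covariate is
#'   present).
#' @export
wtp_at_means <- function(fit, xbar = NULL, mean_variance = FALSE) {
  stopifnot(inherits(fit, "wtp_fit"))
  if (is.null(xbar)) {
    if (is.null(fit$xbar)) stop("fit carries no covariate means; supply xbar")
    xbar <- fit$xbar
  }
  stopifnot(length(xbar) == length(fit$beta))
  point <- drop(sum(xbar * fit$beta))
  V <- fit$vcov_robust
  if (is.null(V)) stop("fit carries no covariance; refit with fit_interval_reg()")
  Vb <- V[names(fit$beta), names(fit$beta), drop = FALSE]
  var_pt <- drop(t(xbar) %*% Vb %*% xbar)
  if (mean_variance && !is.null(fit$data)) {
    X <- fit$data$X
    cov_xbar <- stats::cov(X) / nrow(X)
    var_pt <- var_pt + drop(t(fit$beta) %*% cov_xbar %*% fit$beta)
  }
  se <- sqrt(max(var_pt, 0))
  z <- if (se > 0) point / se else NA_real_
  ref_cost <- if ("current_cost" %in% names(xbar)) unname(xbar["current_cost"]) else NA_real_
  structure(list(
    point = point, se = se, z = z,
    p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
    covariate_means = xbar,
    reference_cost = ref_cost,
    dollars_per_month = point * ref_cost
  ), class = "wtp_estimate")
}

#' @export
print.wtp_estimate <- function(x, ...) {
  cat(sprintf("Mean WTP: %.3f of current cost (robust SE %.3f, z = %.2f, p = %.3g) %s\n",
              x$point, x$se, x$z, x$p, p_stars(x$p)))
  if (!is.na(x$reference_cost)) {
    cat(sprintf("         = $%.2f/month at the sample mean cost of $%.2f\n",
                x$dollars_per_month, x$reference_cost))
  }
  invisible(x)
}

#' Marginal effect of a covariate on predicted WTP
#'
#' The model is linear in covariates, so the change in predicted WTP for a
#' change `delta` in covariate `name` is exactly `beta_hat[name] * delta`
#' (in fraction-of-cost units; multiply by 100 for percentage points).
#'
#' @param fit a `"wtp_fit"` (fitted or built with [wtp_fit_from_coef()]).
#' @param name covariate name.
#' @param delta change in the covariate (e.g. 100 for a $100 higher current
#'   cost, 1 for switching a binary indicator on).
#' @return change in the predicted WTP fraction.
#' @examples
#' fit <- wtp_fit_from_coef(c(current_cost = -1e-4, covid_more_stable = 0.07))
#' marginal_effect(fit, "current_cost", 100)      # -0.01 (1 point lower)
#' marginal_effect(fit, "covid_more_stable", 1)   # +0.07
#' @export
marginal_effect <- function(fit, name, delta = 1) {
  stopifnot(inherits(fit, "wtp_fit"), is.numeric(delta), length(delta) == 1)
  if (!name %in% names(fit$beta)) {
    stop("unknown covariate '", name, "'; available: ",
         paste(names(fit$beta), collapse = ", "))
  }
  unname(fit$beta[name] * delta)
}

#' Format fitted models into a results table
#'
#' Side-by-side per-model columns of coefficients and robust standard
#' errors, with significance stars at the `p <= 0.10` / `0.05` / `0.01`
#' thresholds (inclusive boundaries), followed by `Ln(Sigma)`, the mean-WTP
#' row, the Wald chi-square and the number of observations.
#'
#' @param fits named list of `"wtp_fit"` objects (names become column
#'   labels); may be empty.
#' @param estimates optional named list of [wtp_at_means()] results aligned
#'   with `fits` (computed from each fit when `NULL`).
#' @param stars annotate significance, default `TRUE`.
#' @param digits coefficient digits, default 3.
#' @return data.frame, one row per parameter plus the summary rows; a
#'   header-only frame when `fits` is empty.
#' @export
format_results_table <- function(fits, estimates = NULL, stars = TRUE, digits = 3) {
  if (length(fits) == 0) {
    return(data.frame(term = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  if (is.null(estimates)) estimates <- lapply(fits, wtp_at_means)
  terms <- unique(unlist(lapply(fits, function(f) names(f$beta))))
  terms <- c(setdiff(terms, "(Intercept)"), "(Intercept)")
  fmt <- function(x, star = "") {
    ifelse(is.na(x), "", paste0(formatC(x, digits = digits, format = "f"), star))
  }
  out <- data.frame(term = c(terms, "Ln(Sigma)", "Willingness to pay",
                             "Wald chi2", "Observations"),
                    stringsAsFactors = FALSE)
  for (m in names(fits)) {
    f <- fits[[m]]
    se_all <- sqrt(diag(f$vcov_robust))
    coefs <- ses <- rep(NA_real_, length(terms))
    names(coefs) <- names(ses) <- terms
    coefs[names(f$beta)] <- f$beta
    ses[names(f$beta)] <- se_all[names(f$beta)]
    z <- coefs / ses
    p <- 2 * stats::pnorm(-abs(z))
    st <- if (stars) p_stars(p) else ""
    est <- estimates[[m]]
    lnsig_se <- se_all["ln_sigma"]
    lnsig_p <- 2 * stats::pnorm(-abs(f$ln_sigma / lnsig_se))
    wald_st <- if (stars) p_stars(f$wald_p) else ""
    out[[paste0(m, "_coef")]] <- c(
      fmt(coefs, st),
      fmt(f$ln_sigma, if (stars) p_stars(lnsig_p) else ""),
      fmt(est$point, if (stars) p_stars(est$p) else ""),
      paste0(formatC(f$wald_chi2, digits = 2, format = "f"), wald_st),
      as.character(f$n)
    )
    out[[paste0(m, "_se")]] <- c(
      fmt(ses), fmt(lnsig_se), fmt(est$se), "", ""
    )
  }
  out
}

#' Write a fit (and its WTP estimate) to JSON
#'
#' Machine-readable serialization: coefficients, robust SEs, z, p, stars,
#' `ln_sigma`, Wald test, sample size, convergence, and the mean-WTP
#' prediction.
#'
#' @param fit a `"wtp_fit"`.
#' @param path output path.
#' @param estimate optional [wtp_at_means()] result (computed when `NULL`
#'   and the fit carries data).
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path, estimate = NULL) {
  stopifnot(inherits(fit, "wtp_fit"))
  se <- sqrt(diag(fit$vcov_robust))[names(fit$beta)]
  z <- fit$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (is.null(estimate) && !is.null(fit$data)) estimate <- wtp_at_means(fit)
  obj <- list(
    coefficients = lapply(seq_along(fit$beta), function(i) list(
      term = names(fit$beta)[i], estimate = unname(fit$beta[i]),
      robust_se = unname(se[i]), z = unname(z[i]), p = unname(p[i]),
      stars = p_stars(p[i])
    )),
    ln_sigma = fit$ln_sigma, sigma = fit$sigma,
    loglik = fit$loglik,
    wald = list(chi2 = fit$wald_chi2, df = fit$wald_df, p = fit$wald_p),
    n = fit$n, converged = fit$converged,
    wtp_at_means = if (!is.null(estimate)) {
      list(point = estimate$point, se = estimate$se, z = estimate$z,
           p = estimate$p, dollars_per_month = estimate$dollars_per_month)
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Fit one group's WTP model from respondent records
#'
#' Convenience pipeline reproducing the survey analysis for a single group:
#' classify respondents, keep the group, encode its model covariates,
#' listwise-delete incomplete records, map response sequences to censored
#' intervals, and fit the interval regression.
#'
#' @param records respondent data.frame (see [survey_schema]).
#' @param group `"owner"`, `"boarder"` or `"leaser"`.
#' @param control passed to [fit_interval_reg()].
#' @return a `"wtp_fit"` with an extra `dropped` element describing the
#'   listwise deletion.
#' @export
estimate_group <- function(records, group = c("owner", "boarder", "leaser"),
                           control = list()) {
  group <- match.arg(group)
  cls <- classify_respondent(records, on_unclassifiable = "na")
  sub <- records[!is.na(cls) & cls == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records classified as ", group)
  covars <- encode_covariates(sub, group)
  flt <- listwise_filter(sub, covars)
  iv <- map_to_interval(flt$records$response1, flt$records$response2,
                        flt$records$followup_frac)
  X <- cbind("(Intercept)" = 1, as.matrix(flt$covars))
  fit <- fit_interval_reg(iv$lower, iv$upper, X, control = control)
  fit$group <- group
  fit$dropped <- list(n = flt$n_dropped, by_field = flt$dropped_by_field)
  fit
}
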