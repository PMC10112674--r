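# Internal numeric helpers shared across modules.

#' Round money half-up to cents
#'
#' Commercial rounding for dollar amounts shown to respondents: exact halves
#' round away from the floor (`round()` in R rounds half to even, which is
#' wrong for prices).  Analysis quantities are never rounded.
#'
#' @param x numeric vector of dollar amounts.
#' @return `x` rounded to two decimals with ties going up.
#' @examples
#' round_money(260.117) # 260.12
#' round_money(0.125)   # 0.13, not 0.12
#' @export
round_money <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

# log(1 - exp(x)) for x <= 0, numerically stable (Maechler's two-branch form)
log1mexp <- function(x) {
  stopifnot(all(x <= 0 | is.nan(x)))
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# log(Phi(b) - Phi(a)) for a < b, stable in both tails.  Works elementwise;
# a may be -Inf and b may be +Inf.
log_pnorm_diff <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- numeric(length(a))
  # reflect so that the pair lies in the lower tail, where pnorm(log.p) is
  # accurate: if the interval sits in the upper tail, use symmetry
  flip <- (a + b) > 0 & is.finite(a + b) | (is.infinite(a) & a > 0) |
    (is.infinite(b) & b > 0 & is.infinite(a))
  flip[is.na(flip)] <- FALSE
  aa <- ifelse(flip, -b, a)
  bb <- ifelse(flip, -a, b)
  lo <- stats::pnorm(aa, log.p = TRUE)
  hi <- stats::pnorm(bb, log.p = TRUE)
  ifelse(bb == Inf & aa == -Inf, 0,
    ifelse(aa == -Inf, hi, hi + log1mexp(pmin(lo - hi, 0)))
  )
}

# significance stars at the conventional survey-econometrics thresholds,
# inclusive at each boundary (p <= 0.05 earns "**")
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi <= 0.01) "***" else if (pi <= 0.05) "**" else if (pi <= 0.10) "*" else ""
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
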