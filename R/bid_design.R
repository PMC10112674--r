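# Double-bounded dichotomous-choice bid design.
#
# Every respondent is first offered a bid equal to a 10% increase over their
# current monthly cost of care.  A "yes" triggers a follow-up bid drawn
# uniformly from the integer percents 11..20; a "no" triggers a follow-up
# drawn from 1..9.  The two answers bracket the latent willingness to pay
# (WTP), expressed throughout as a *fraction of current cost*, in a censored
# interval.  Dollar conversion is a reporting convenience only.

#' Bid schedule constants
#'
#' The three bid fractions of the double-bounded design: the common first bid
#' `c1` (0.10), and the supports of the randomized follow-up bids after a yes
#' (`c2y`, 0.11 to 0.20 by 0.01) and after a no (`c2n`, 0.01 to 0.09 by 0.01).
#'
#' @return a list with elements `c1` (scalar), `c2y_support`, `c2n_support`
#'   (numeric vectors of legal follow-up fractions).
#' @examples
#' bid_schedule()$c1
#' @export
bid_schedule <- function() {
  list(
    c1 = 0.10,
    c2y_support = seq(0.11, 0.20, by = 0.01),
    c2n_support = seq(0.01, 0.09, by = 0.01)
  )
}

#' First bid in dollars
#'
#' Dollar amount of the initial bid shown to a respondent: a 10% increase on
#' the current monthly cost, rounded half-up to cents as a price would be.
#' A zero current cost produces a degenerate $0 bid and a warning, since the
#' respondent is then being offered no change at all.
#'
#' @param current_cost numeric vector of current monthly costs (USD, >= 0).
#' @return dollar amounts `current_cost * 1.10`, rounded to cents.
#' @examples
#' first_bid_dollars(400)    # 440
#' first_bid_dollars(236.47) # 260.12
#' @export
first_bid_dollars <- function(current_cost) {
  if (any(is.na(current_cost)) || any(current_cost < 0)) {
    stop("current_cost must be non-negative and non-missing")
  }
  if (any(current_cost == 0)) {
    warning("current cost of 0 produces a degenerate $0 bid")
  }
  round_money(current_cost * (1 + bid_schedule()$c1))
}

#' Draw follow-up bid fractions
#'
#' Randomized second bid: discrete uniform over the integer percents 11..20
#' after a "yes" to the first bid, 1..9 after a "no" (both endpoints
#' inclusive).  Uses R's RNG, so draws are reproducible under `set.seed()`.
#'
#' @param response1 character vector of `"yes"`/`"no"` first responses.
#' @return numeric vector of follow-up bid fractions, same length.
#' @examples
#' set.seed(1)
#' draw_followup(c("yes", "no", "no"))
#' @export
draw_followup <- function(response1) {
  response1 <- match.arg(response1, c("yes", "no"), several.ok = TRUE)
  sched <- bid_schedule()
  out <- numeric(length(response1))
  for (i in seq_along(response1)) {
    sup <- if (response1[i] == "yes") sched$c2y_support else sched$c2n_support
    out[i] <- sup[sample.int(length(sup), 1L)]
  }
  round(out, 2)
}

#' Map a response sequence to a censored WTP interval
#'
#' Converts the pair of yes/no answers plus the realized follow-up bid into
#' the censored interval known to contain the latent WTP fraction, with the
#' convention `lower <= WTP < upper`:
#'
#' * (yes, yes): `[c2y, +Inf)` — right-censored;
#' * (yes, no):  `[0.10, c2y)`;
#' * (no, yes):  `[c2n, 0.10)`;
#' * (no, no):   `(-Inf, c2n)` — left-censored (the lower bound is
#'   unrestrained; negative latent WTP is admissible).
#'
#' @param response1,response2 character vectors of `"yes"`/`"no"`.
#' @param followup_frac realized follow-up fractions; must lie in the support
#'   implied by `response1`.
#' @return data.frame with columns `lower`, `upper` (fractions of current
#'   cost, possibly infinite) and `censoring` (`"interval"`, `"left"`,
#'   `"right"`).
#' @examples
#' map_to_interval("yes", "no", 0.15)  # [0.10, 0.15)
#' map_to_interval("no", "yes", 0.05)  # [0.05, 0.10)
#' @export
map_to_interval <- function(response1, response2, followup_frac) {
  n <- length(response1)
  stopifnot(length(response2) == n, length(followup_frac) == n)
  r1 <- match.arg(response1, c("yes", "no"), several.ok = TRUE)
  r2 <- match.arg(response2, c("yes", "no"), several.ok = TRUE)
  sched <- bid_schedule()
  tol <- 1e-9
  ok_yes <- abs(outer(followup_frac, sched$c2y_support, "-")) < tol
  ok_no <- abs(outer(followup_frac, sched$c2n_support, "-")) < tol
  legal <- ifelse(r1 == "yes", rowSums(ok_yes) > 0, rowSums(ok_no) > 0)
  if (!all(legal)) {
    stop(
      "follow-up fraction inconsistent with first response at row(s): ",
      paste(which(!legal), collapse = ", ")
    )
  }
  lower <- ifelse(r1 == "yes",
    ifelse(r2 == "yes", followup_frac, sched$c1),
    ifelse(r2 == "yes", followup_frac, -Inf)
  )
  upper <- ifelse(r1 == "yes",
    ifelse(r2 == "yes", Inf, followup_frac),
    ifelse(r2 == "yes", sched$c1, followup_frac)
  )
  censoring <- ifelse(is.infinite(lower), "left",
    ifelse(is.infinite(upper), "right", "interval")
  )
  data.frame(lower = lower, upper = upper, censoring = censoring,
             stringsAsFactors = FALSE)
}

#' Convert a WTP interval from fractions to dollars per month
#'
#' Scales interval bounds by the respondent's current cost, preserving the
#' censoring type.  With a current cost of zero the dollar interval is
#' degenerate (every bound collapses to 0) and is flagged rather than
#' returned as if informative.
#'
#' @param interval data.frame as returned by [map_to_interval()].
#' @param current_cost numeric vector of current monthly costs (USD).
#' @return data.frame with `lower`, `upper` in additional USD/month,
#'   `censoring`, and logical `degenerate` marking zero-cost rows.
#' @export
interval_in_dollars <- function(interval, current_cost) {
  stopifnot(nrow(interval) == length(current_cost), all(current_cost >= 0))
  degen <- current_cost == 0
  out <- data.frame(
    lower = interval$lower * current_cost,
    upper = interval$upper * current_cost,
    censoring = interval$censoring,
    degenerate = degen,
    stringsAsFactors = FALSE
  )
  # 0 * Inf is NaN; restore the censored bound before flagging
  out$lower[degen] <- ifelse(is.infinite(interval$lower[degen]), -Inf, 0)
  out$upper[degen] <- ifelse(is.infinite(interval$upper[degen]), Inf, 0)
  if (any(degen)) warning("zero current cost gives a degenerate dollar interval")
  out
}
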