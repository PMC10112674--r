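# Shared fixtures, all generated in code.

# a small respondent data.frame covering the three groups
make_records <- function() {
  data.frame(
    id = sprintf("r%02d", 1:6),
    owns_at_home_count = c("2-4", "1", "0", "0", "5-9", "0"),
    boards_count = c("0", "0", "2-4", "0", "0", "1"),
    leases_count = c("1", "0", "0", "1", "0", "0"),
    current_cost = c(200, 400, 514.75, 0, 719, 236.47),
    lease_type = c("full", "none", "none", "free", "none", "none"),
    board_type = c("none", "none", "full", "none", "none", "partial"),
    disc_sport = c(1, 0, 1, 0, 0, 1),
    disc_ranch_western = c(0, 1, 0, 0, 0, 0),
    disc_other = c(0, 0, 0, 1, 0, 0),
    covid_stability = c("more", "same", "less", "more", "same", "more"),
    sell_or_stop_intent = c("no", "yes", "maybe", "no", "no", "no"),
    region = c("south", "other", "south", "south", "other", "south"),
    income_bracket = c("100-150k", "50-75k", ">150k", "0-25k", "75-100k", "25-50k"),
    age_bracket = c("25-34", "45-54", "18-24", "35-44", "55-64", "65-74"),
    sex = c("female", "female", "male", "female", "female", "female"),
    response1 = c("yes", "yes", "no", "no", "yes", "no"),
    response2 = c("yes", "no", "yes", "no", "yes", "no"),
    followup_frac = c(0.15, 0.12, 0.05, 0.03, 0.20, 0.07),
    stringsAsFactors = FALSE
  )
}

# simulate an intercept-only interval dataset with known truth
sim_intercept_data <- function(n, mu, sigma, seed = 1) {
  set.seed(seed)
  w <- rnorm(n, mu, sigma)
  resp <- simulate_responses(w)
  map_to_interval(resp$response1, resp$response2, resp$followup_frac)
}

# brute-force grid maximizer of the interval log-likelihood over
# (beta0, ln_sigma); the independent oracle for intercept-only fits
grid_fit_intercept <- function(lower, upper, beta_range, lnsig_range, step) {
  b_grid <- seq(beta_range[1], beta_range[2], by = step)
  t_grid <- seq(lnsig_range[1], lnsig_range[2], by = step)
  best <- c(NA, NA, -Inf)
  for (b in b_grid) {
    for (t in t_grid) {
      ll <- sum(obs_loglik(lower, upper, b, t))
      if (ll > best[3]) best <- c(b, t, ll)
    }
  }
  list(beta0 = best[1], ln_sigma = best[2], loglik = best[3], step = step)
}
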