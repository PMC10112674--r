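# Calibrated synthetic survey generator.
#
# Generates owner/boarder/leaser respondent populations with the statistical
# structure the estimator assumes: independent binary/categorical covariates
# at configured frequencies, log-normal monthly care costs (with a point
# mass at $0 for free arrangements), latent WTP fractions from the linear
# normal model, and double-bounded bid responses simulated through the same
# bid schedule the survey used.  Everything is driven by one config object
# so estimation, inference and reporting can be validated end to end against
# known truth.

.split_5p <- c("5-9" = 0.7, "10-19" = 0.2, "20+" = 0.1)

.default_group_config <- function(group) {
  shared <- list(
    p_south = 0.73,
    income_probs = c("0-25k" = 0.07, "25-50k" = 0.20, "50-75k" = 0.17,
                     "75-100k" = 0.18, "100-150k" = 0.21, ">150k" = 0.17),
    age_probs = c("18-24" = 0.133, "25-34" = 0.195, "35-44" = 0.204,
                  "45-54" = 0.198, "55-64" = 0.189, "65-74" = 0.077,
                  "75-84" = 0.004),
    p_female = 0.93,
    covid_probs = c(less = 0.03, same = 0.41, more = 0.56),
    sell_probs = c(yes = 0.07, maybe = 0.09, no = 0.84),
    disc_probs = c(sport = 0.28, ranch_western = 0.10, other = 0.14),
    p_missing_income = 0.13,
    p_missing_age = 0.11,
    p_missing_sex = 0.11
  )
  per_group <- switch(group,
    owner = list(
      n = 292,
      count_probs = c("1" = 0.25, "2-4" = 0.45, "5+" = 0.30),
      type_probs = NULL,
      cost = list(mean = 406.37, sd = 606.40, max = 6000, zero_frac = 0.02),
      sigma = 0.15, target_mean_wtp = 0.26,
      beta = c(current_cost = 0, own_lease_2_4 = -0.02, own_lease_5p = -0.07,
               sport = 0.01, ranch_western = 0.04, other_disciplines = 0.02,
               covid_less_stable = -0.04, covid_more_stable = 0.07,
               sell_yes = -0.10, sell_maybe = -0.04, south = -0.11,
               ahi_gt_75k = 0.09, age_lt_35 = 0.03)
    ),
    boarder = list(
      n = 282,
      count_probs = c("1" = 0.40, "2-4" = 0.45, "5+" = 0.15),
      type_probs = c(free = 0.05, partial = 0.27, full = 0.63, other = 0.05),
      cost = list(mean = 391.42, sd = 285.45, max = 1500, zero_frac = 0.05),
      sigma = 0.08, target_mean_wtp = 0.02,
      beta = c(current_cost = -1e-04, own_lease_2_4 = -0.06, own_lease_5p = 0.02,
               partial_board_or_lease = 0.09, full_board_or_lease = 0.07,
               sport = 0.02, ranch_western = -0.01, other_disciplines = 0.11,
               covid_less_stable = 0.05, covid_more_stable = 0.01,
               sell_yes = 0.02, sell_maybe = -0.03, south = 0.02,
               ahi_gt_75k = 0.04, age_lt_35 = -0.03)
    ),
    leaser = list(
      n = 79,
      count_probs = c("1" = 0.76, "2-4" = 0.18, "5+" = 0.06),
      type_probs = c(free = 0.35, partial = 0.33, full = 0.25, other = 0.07),
      p_leaser_owns = 0.54,
      cost = list(mean = 190.22, sd = 211.19, max = 750, zero_frac = 0.10),
      sigma = 0.12, target_mean_wtp = 0.20,
      # slope magnitudes are capped near 0.12 so that no subgroup's mean is
      # pushed entirely outside the 1-20% bid ladder: a coefficient that
      # moves a subgroup to always-yes-yes (or always-no-no) responses is
      # unidentifiable under this design
      beta = c(current_cost = 0, own_lease_2_4 = 0.08, own_lease_5p = 0.12,
               leaser_who_owns = -0.04, partial_board_or_lease = 0.00,
               full_board_or_lease = 0.10, covid_less_stable = 0.10,
               covid_more_stable = 0.00, sell_yes = 0.06, sell_maybe = 0.11,
               south = -0.03, ahi_gt_75k = 0.04, age_lt_35 = -0.01)
    )
  )
  utils::modifyList(shared, per_group)
}

#' Build a synthetic-survey configuration
#'
#' Returns the full configuration of the generator: per-group sample sizes,
#' covariate frequencies, cost-distribution targets, the true coefficient
#' vectors and error scales of the latent WTP model, and the seed.  The
#' `"table1-like"` preset is calibrated so covariate and cost moments match
#' the published survey summaries and the true parameters echo the response
#' mix of the three groups (owners mostly yes-yes, boarders mostly no-no);
#' its parameter values are presets of this generator, not estimates.
#'
#' Each group's intercept is derived at construction so that the expected
#' latent mean WTP equals `target_mean_wtp` given the configured covariate
#' frequencies.
#'
#' @param preset currently `"table1-like"`.
#' @param seed integer RNG seed stored in the config.
#' @param overrides nested named list merged over the preset (e.g.
#'   `list(owner = list(n = 5000))`).
#' @return object of class `"wtp_syn_config"`: list with elements `owner`,
#'   `boarder`, `leaser` and `seed`.
#' @export
synthetic_config <- function(preset = "table1-like", seed = 1L, overrides = list()) {
  preset <- match.arg(preset)
  cfg <- list(
    owner = .default_group_config("owner"),
    boarder = .default_group_config("boarder"),
    leaser = .default_group_config("leaser"),
    seed = as.integer(seed)
  )
  cfg <- utils::modifyList(cfg, overrides)
  for (g in c("owner", "boarder", "leaser")) {
    gc <- cfg[[g]]
    .validate_probs(gc, g)
    cfg[[g]]$intercept <- gc$target_mean_wtp -
      sum(gc$beta * .expected_covariate_means(gc, g)[names(gc$beta)])
  }
  structure(cfg, class = "wtp_syn_config")
}

.validate_probs <- function(gc, group) {
  blocks <- list(count_probs = gc$count_probs, covid_probs = gc$covid_probs,
                 sell_probs = gc$sell_probs, income_probs = gc$income_probs,
                 age_probs = gc$age_probs)
  if (!is.null(gc$type_probs)) blocks$type_probs <- gc$type_probs
  for (nm in names(blocks)) {
    p <- blocks[[nm]]
    if (any(p < 0) || sum(p) > 1 + 1e-8) {
      stop(group, " config block '", nm, "' has probabilities outside [0,1] or summing > 1")
    }
  }
  stopifnot(gc$sigma > 0, gc$cost$mean > 0, gc$cost$sd > 0)
}

# expected value of each model covariate under the config (independence)
.expected_covariate_means <- function(gc, group) {
  m <- c(
    current_cost = (1 - gc$cost$zero_frac) * gc$cost$mean,
    own_lease_2_4 = unname(gc$count_probs["2-4"]),
    own_lease_5p = unname(gc$count_probs["5+"]),
    covid_less_stable = unname(gc$covid_probs["less"]),
    covid_more_stable = unname(gc$covid_probs["more"]),
    sell_yes = unname(gc$sell_probs["yes"]),
    sell_maybe = unname(gc$sell_probs["maybe"]),
    south = gc$p_south,
    ahi_gt_75k = sum(gc$income_probs[c("75-100k", "100-150k", ">150k")]) /
      sum(gc$income_probs),
    age_lt_35 = sum(gc$age_probs[c("18-24", "25-34")]) / sum(gc$age_probs),
    sport = unname(gc$disc_probs["sport"]),
    ranch_western = unname(gc$disc_probs["ranch_western"]),
    other_disciplines = unname(gc$disc_probs["other"])
  )
  if (!is.null(gc$type_probs)) {
    m <- c(m, partial_board_or_lease = unname(gc$type_probs["partial"]),
           full_board_or_lease = unname(gc$type_probs["full"]))
  }
  if (group == "leaser") m <- c(m, leaser_who_owns = gc$p_leaser_owns)
  m
}

#' Read a synthetic-survey configuration from YAML
#'
#' Loads a YAML file of overrides and merges it over the named preset, so a
#' config file only needs to state what differs.
#'
#' @param path YAML file; top-level keys `preset`, `seed` and any of
#'   `owner`/`boarder`/`leaser` blocks.
#' @return a [synthetic_config()] object.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (g in intersect(names(y), c("owner", "boarder", "leaser"))) {
    # YAML 1.1 implicitly types a bare key `n` as boolean FALSE; undo that
    names(y[[g]])[names(y[[g]]) == "FALSE"] <- "n"
    for (nm in intersect(names(y[[g]]), c("beta", "count_probs", "type_probs",
                                          "covid_probs", "sell_probs",
                                          "disc_probs", "income_probs",
                                          "age_probs"))) {
      y[[g]][[nm]] <- unlist(y[[g]][[nm]])
    }
  }
  synthetic_config(
    preset = y$preset %||% "table1-like",
    seed = y$seed %||% 1L,
    overrides = y[intersect(names(y), c("owner", "boarder", "leaser"))]
  )
}

#' Log-normal parameters matching a target mean and SD
#'
#' Closed-form moment inversion: for target moments `(m, s)` of a log-normal
#' variate, `sdlog^2 = log(1 + (s/m)^2)` and
#' `meanlog = log(m) - sdlog^2 / 2`.
#'
#' @param mean,sd target arithmetic mean and standard deviation (`> 0`).
#' @return list with `meanlog`, `sdlog`.
#' @examples
#' p <- lognormal_params(406.37, 606.40)
#' exp(p$meanlog + p$sdlog^2 / 2) # 406.37
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

.draw_bin <- function(n, class_probs) {
  cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
  fine <- cls
  is5 <- cls == "5+"
  if (any(is5)) {
    fine[is5] <- sample(names(.split_5p), sum(is5), replace = TRUE, prob = .split_5p)
  }
  fine
}

#' Generate monthly care costs for one group
#'
#' Zero with probability `zero_frac` (free arrangements), otherwise
#' log-normal with parameters solved from the configured target mean/SD by
#' [lognormal_params()], redrawn while above the configured maximum, and
#' rounded to cents.  Uses the ambient RNG state.
#'
#' @param gcfg one group's block of a [synthetic_config()].
#' @param n number of draws.
#' @return numeric vector of USD/month values.
#' @export
generate_costs <- function(gcfg, n) {
  cp <- gcfg$cost
  lp <- lognormal_params(cp$mean, cp$sd)
  x <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  for (it in 1:100) {
    over <- x > cp$max
    if (!any(over)) break
    x[over] <- stats::rlnorm(sum(over), lp$meanlog, lp$sdlog)
  }
  x[x > cp$max] <- cp$max
  x[stats::runif(n) < cp$zero_frac] <- 0
  round_money(x)
}

#' Generate respondent covariates and costs for all groups
#'
#' Draws each group's records from its configured frequencies: mutually
#' exclusive blocks (equid-count bins, lease/board type, pandemic impact,
#' sale intent, income and age brackets) are drawn categorically so at most
#' one indicator per block is set; the remaining flags are independent
#' Bernoulli draws.  Responses are not filled in (see
#' [simulate_responses()] / [end_to_end_dataset()]).  Uses the ambient RNG
#' state; seed handling belongs to the caller.
#'
#' @param config a [synthetic_config()].
#' @return respondent data.frame in the documented schema with `response1`,
#'   `response2`, `followup_frac` set to `NA`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "wtp_syn_config"))
  out <- lapply(c("owner", "boarder", "leaser"), function(g) {
    gc <- config[[g]]
    n <- gc$n
    if (n == 0) return(NULL)
    bin <- .draw_bin(n, gc$count_probs)
    owns <- boards <- leases <- rep("0", n)
    lease_type <- board_type <- rep("none", n)
    if (g == "owner") {
      owns <- bin
    } else if (g == "boarder") {
      boards <- bin
      board_type <- sample(names(gc$type_probs), n, TRUE, gc$type_probs)
    } else {
      leases <- bin
      lease_type <- sample(names(gc$type_probs), n, TRUE, gc$type_probs)
      also_owns <- stats::runif(n) < gc$p_leaser_owns
      owns[also_owns] <- .draw_bin(sum(also_owns), gc$count_probs)
    }
    inc <- sample(names(gc$income_probs), n, TRUE, gc$income_probs)
    age <- sample(names(gc$age_probs), n, TRUE, gc$age_probs)
    sex <- ifelse(stats::runif(n) < gc$p_female, "female", "male")
    df <- data.frame(
      id = sprintf("%s_%05d", g, seq_len(n)),
      owns_at_home_count = owns, boards_count = boards, leases_count = leases,
      current_cost = generate_costs(gc, n),
      lease_type = lease_type, board_type = board_type,
      disc_sport = as.numeric(stats::runif(n) < gc$disc_probs["sport"]),
      disc_ranch_western = as.numeric(stats::runif(n) < gc$disc_probs["ranch_western"]),
      disc_other = as.numeric(stats::runif(n) < gc$disc_probs["other"]),
      covid_stability = sample(names(gc$covid_probs), n, TRUE, gc$covid_probs),
      sell_or_stop_intent = sample(names(gc$sell_probs), n, TRUE, gc$sell_probs),
      region = ifelse(stats::runif(n) < gc$p_south, "south", "other"),
      income_bracket = inc, age_bracket = age, sex = sex,
      response1 = NA_character_, response2 = NA_character_,
      followup_frac = NA_real_,
      stringsAsFactors = FALSE
    )
    df
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' True parameters of a configured group model
#'
#' @param config a [synthetic_config()].
#' @param group `"owner"`, `"boarder"` or `"leaser"`.
#' @return list with `beta` (named, `(Intercept)` first, ordered as
#'   [model_covariates()]) and `sigma`.
#' @export
true_parameters <- function(config, group = c("owner", "boarder", "leaser")) {
  group <- match.arg(group)
  gc <- config[[group]]
  beta <- c("(Intercept)" = gc$intercept, gc$beta[model_covariates(group)])
  list(beta = beta, sigma = gc$sigma)
}

#' Draw latent WTP fractions
#'
#' The latent linear model: `w = x'beta + eps`, `eps ~ Normal(0, sigma^2)`.
#' Negative draws are legitimate (the left tail exists; the bid design
#' leaves the double-no lower bound unrestrained).
#'
#' @param X design matrix or covariate data.frame (intercept column added if
#'   absent when `beta` is one element longer than `ncol(X)`).
#' @param beta coefficient vector, intercept first.
#' @param sigma error scale `>= 0`.
#' @return numeric vector of WTP fractions.
#' @export
generate_latent_wtp <- function(X, beta, sigma) {
  stopifnot(sigma >= 0)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (ncol(X) == length(beta) - 1) X <- cbind(1, X)
  stopifnot(ncol(X) == length(beta))
  drop(X %*% beta) + stats::rnorm(nrow(X), 0, sigma)
}

#' Simulate double-bounded bid responses from latent WTP
#'
#' Applies the bid schedule to each latent fraction: the first answer is
#' "yes" iff `w >= 0.10` (ties count as yes throughout); the follow-up bid
#' is drawn by [draw_followup()] unless supplied, and the second answer
#' compares `w` to it the same way.
#'
#' @param w latent WTP fractions.
#' @param followup_frac optional realized follow-up fractions (must be legal
#'   for the implied first response); drawn if `NULL`.
#' @return data.frame with `response1`, `response2`, `followup_frac`.
#' @export
simulate_responses <- function(w, followup_frac = NULL) {
  c1 <- bid_schedule()$c1
  r1 <- ifelse(w >= c1, "yes", "no")
  if (is.null(followup_frac)) followup_frac <- draw_followup(r1)
  r2 <- ifelse(w >= followup_frac, "yes", "no")
  # guard the schedule invariant
  map_to_interval(r1, r2, followup_frac)
  data.frame(response1 = r1, response2 = r2, followup_frac = followup_frac,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic survey dataset
#'
#' End-to-end generator: seeds the RNG from the config, draws covariates and
#' costs, computes each respondent's latent WTP from the group's true
#' coefficients, simulates the double-bounded responses, then (last, so the
#' latent model is unaffected) masks income/age/sex at the configured
#' missingness rates.  The returned oracle table records the latent truth
#' per respondent for recovery tests; it is synthetic ground truth, not
#' survey data.
#'
#' @param config a [synthetic_config()].
#' @param path optional CSV path for the respondent table.
#' @param oracle_path optional CSV path for the oracle sidecar.
#' @return list with `records` (respondent data.frame), `oracle`
#'   (data.frame: `id`, `group`, `mu`, `w`, `sigma`), and `config`.
#' @export
end_to_end_dataset <- function(config, path = NULL, oracle_path = NULL) {
  stopifnot(inherits(config, "wtp_syn_config"))
  if (config$owner$n + config$boarder$n + config$leaser$n == 0) {
    stop("empty dataset: all group sizes are zero")
  }
  set.seed(config$seed)
  records <- generate_covariates(config)
  group <- classify_respondent(records)
  oracle <- vector("list", 3)
  names(oracle) <- c("owner", "boarder", "leaser")
  for (g in names(oracle)) {
    idx <- which(group == g)
    if (!length(idx)) next
    tp <- true_parameters(config, g)
    X <- cbind("(Intercept)" = 1, as.matrix(encode_covariates(records[idx, ], g)))
    w <- generate_latent_wtp(X, tp$beta, tp$sigma)
    resp <- simulate_responses(w)
    records$response1[idx] <- resp$response1
    records$response2[idx] <- resp$response2
    records$followup_frac[idx] <- resp$followup_frac
    oracle[[g]] <- data.frame(
      id = records$id[idx], group = g, mu = drop(X %*% tp$beta),
      w = w, sigma = tp$sigma, stringsAsFactors = FALSE
    )
  }
  oracle <- do.call(rbind, Filter(Negate(is.null), oracle))
  rownames(oracle) <- NULL
  # MCAR missingness applied after the response process
  for (g in c("owner", "boarder", "leaser")) {
    idx <- which(group == g)
    gc <- config[[g]]
    mi <- idx[stats::runif(length(idx)) < gc$p_missing_income]
    ma <- idx[stats::runif(length(idx)) < gc$p_missing_age]
    ms <- idx[stats::runif(length(idx)) < gc$p_missing_sex]
    records$income_bracket[mi] <- NA
    records$age_bracket[ma] <- NA
    records$sex[ms] <- NA
  }
  if (!is.null(path)) write_respondents(records, path)
  if (!is.null(oracle_path)) utils::write.csv(oracle, oracle_path, row.names = FALSE)
  list(records = records, oracle = oracle, config = config)
}
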