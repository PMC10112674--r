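test_that("log-normal moment inversion satisfies the back-transform identity", {
  for (m in c(50, 190.22, 406.37)) {
    for (s in c(30, 211.19, 606.40)) {
      p <- lognormal_params(m, s)
      expect_equal(exp(p$meanlog + p$sdlog^2 / 2), m, tolerance = 1e-12)
      expect_equal((exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2), s^2,
                   tolerance = 1e-8)
    }
  }
  expect_error(lognormal_params(100, -1))
})

test_that("generated costs honor the zero mass, cap and target moments", {
  cfg <- synthetic_config(seed = 1)
  gc <- cfg$owner
  set.seed(2)
  gc$cost$zero_frac <- 1
  expect_true(all(generate_costs(gc, 50) == 0))
  gc$cost$zero_frac <- 0
  x <- generate_costs(gc, 2e4)
  expect_true(all(x <= gc$cost$max))
  expect_true(all(x == round_money(x)))
  # moment match on the untruncated component
  gc$cost$max <- Inf
  set.seed(3)
  y <- generate_costs(gc, 1e5)
  expect_lt(abs(mean(y) - 406.37), 3 * 606.40 / sqrt(1e5))
  expect_lt(abs(sd(y) / 606.40 - 1), 0.05)
})

test_that("covariates hit configured frequencies and blocks stay exclusive", {
  cfg <- synthetic_config(seed = 5, overrides = list(
    owner = list(n = 10000), boarder = list(n = 2000), leaser = list(n = 2000)
  ))
  set.seed(5)
  rec <- generate_covariates(cfg)
  own <- rec[grepl("^owner", rec$id), ]
  mc3 <- 3 * sqrt(0.73 * 0.27 / nrow(own))
  expect_lt(abs(mean(own$region == "south") - 0.73), mc3)
  x <- encode_covariates(own, "owner")
  expect_true(all(x$own_lease_2_4 + x$own_lease_5p <= 1))
  expect_lt(abs(mean(x$ahi_gt_75k) - 0.56), 3 * sqrt(0.56 * 0.44 / nrow(own)))
  expect_lt(abs(mean(x$age_lt_35) - 0.328), 3 * sqrt(0.33 * 0.67 / nrow(own)))
  # boarders have a board type, never a lease type; owners neither
  brd <- rec[grepl("^boarder", rec$id), ]
  expect_true(all(brd$lease_type == "none"))
  expect_true(all(brd$board_type %in% c("free", "partial", "full", "other")))
  expect_true(all(own$board_type == "none"))
  # forcing a frequency to 1 pins the indicator
  cfg1 <- synthetic_config(seed = 5, overrides = list(owner = list(p_south = 1)))
  set.seed(1)
  rec1 <- generate_covariates(cfg1)
  expect_true(all(rec1$region[grepl("^owner", rec1$id)] == "south"))
})

test_that("invalid probability blocks are rejected", {
  expect_error(
    synthetic_config(overrides = list(owner = list(
      covid_probs = c(less = 0.8, same = 0.4, more = 0.3)
    ))),
    "summing > 1"
  )
})

test_that("latent WTP draws follow the linear normal model", {
  X <- cbind(1, rbinom(1e5, 1, 0.5))
  beta <- c(0.20, 0.0)
  expect_equal(generate_latent_wtp(X, beta, 0), rep(0.20, 1e5))
  set.seed(4)
  w <- generate_latent_wtp(X, c(0.20, 0), 0.05)
  expect_lt(abs(mean(w) - 0.20), 3 * 0.05 / sqrt(1e5))
  expect_lt(abs(sd(w) - 0.05), 0.001)
  set.seed(4)
  w0 <- generate_latent_wtp(X, c(0, 0), 0.05)
  expect_lt(abs(mean(w0)), 3 * 0.05 / sqrt(1e5))
})

test_that("simulated responses follow the threshold rules with yes-ties", {
  resp <- simulate_responses(c(0.25, 0.07), followup_frac = c(0.20, 0.05))
  expect_equal(resp$response1, c("yes", "no"))
  expect_equal(resp$response2, c("yes", "yes"))
  # a latent WTP exactly at a bid counts as yes
  tie <- simulate_responses(0.10, followup_frac = 0.11)
  expect_equal(tie$response1, "yes")
  tie2 <- simulate_responses(0.15, followup_frac = 0.15)
  expect_equal(tie2$response2, "yes")
})

test_that("empirical sequence frequencies match the analytic probabilities", {
  set.seed(14)
  mu <- 0.12; sigma <- 0.07; c2y <- 0.16; c2n <- 0.04
  w <- rnorm(2e4, mu, sigma)
  f <- ifelse(w >= 0.10, c2y, c2n)
  resp <- simulate_responses(w, followup_frac = f)
  emp <- table(factor(paste(resp$response1, resp$response2, sep = "_"),
                      levels = c("yes_yes", "yes_no", "no_yes", "no_no")))
  p <- sequence_probabilities(mu, sigma, c2y, c2n)
  gof <- chisq.test(emp, p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("every simulated latent WTP lies inside its mapped interval", {
  cfg <- synthetic_config(seed = 10)
  ds <- end_to_end_dataset(cfg)
  iv <- map_to_interval(ds$records$response1, ds$records$response2,
                        ds$records$followup_frac)
  w <- ds$oracle$w[match(ds$records$id, ds$oracle$id)]
  expect_true(all(w >= iv$lower & w < iv$upper))
})

test_that("generation is bit-exact under a fixed config and seed", {
  cfg <- synthetic_config(seed = 99)
  d1 <- end_to_end_dataset(cfg)
  d2 <- end_to_end_dataset(cfg)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$oracle, d2$oracle)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  end_to_end_dataset(cfg, path = p1)
  end_to_end_dataset(cfg, path = p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated datasets round-trip through the survey reader", {
  cfg <- synthetic_config(seed = 8, overrides = list(
    owner = list(n = 60), boarder = list(n = 60), leaser = list(n = 30)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  ds <- end_to_end_dataset(cfg, path = path)
  back <- read_respondents(path)
  expect_equal(back, ds$records)
  expect_error(end_to_end_dataset(synthetic_config(overrides = list(
    owner = list(n = 0), boarder = list(n = 0), leaser = list(n = 0)
  ))), "empty dataset")
})

test_that("intercepts are calibrated to the target mean WTP", {
  cfg <- synthetic_config(seed = 44, overrides = list(
    owner = list(n = 20000), boarder = list(n = 20000), leaser = list(n = 20000)
  ))
  ds <- end_to_end_dataset(cfg)
  for (g in c("owner", "boarder", "leaser")) {
    mu <- ds$oracle$mu[ds$oracle$group == g]
    expect_lt(abs(mean(mu) - cfg[[g]]$target_mean_wtp), 0.015)
  }
})

test_that("YAML configs merge over the preset", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 123",
    "owner:",
    "  n: 42",
    "  sigma: 0.2"
  ), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$seed, 123L)
  expect_equal(cfg$owner$n, 42)
  expect_equal(cfg$owner$sigma, 0.2)
  # untouched blocks keep preset values
  expect_equal(cfg$boarder$n, 282)
  expect_equal(unname(cfg$owner$beta["south"]), -0.11)
})
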