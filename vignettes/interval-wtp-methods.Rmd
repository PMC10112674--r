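---
title: "Methods: double-bounded WTP estimation by interval-censored regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double-bounded WTP estimation by interval-censored regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiwtp)
```

## The elicitation design and the latent model

`equiwtp` analyzes contingent-valuation surveys in which equine owners,
boarders and leasers are asked whether they would pay an increased monthly
cost for their animals' essential care.  Every respondent faces two yes/no
bids expressed as percentage increases over their own current monthly cost:
a first bid of 10%, then a randomized follow-up of 11–20% after a "yes" or
1–9% after a "no" (integer percents, both endpoints inclusive, drawn
uniformly).  The two answers bracket the respondent's latent maximum
willingness to pay (WTP), expressed throughout as a *fraction of current
cost*:

* (yes, yes): WTP ≥ the follow-up bid — right-censored;
* (yes, no): 0.10 ≤ WTP < follow-up;
* (no, yes): follow-up ≤ WTP < 0.10;
* (no, no): WTP < the follow-up bid — left-censored, with an *unrestrained*
  lower bound (negative latent WTP is admissible; a `--floor-zero`-style
  truncation at 0 can be imposed through the interval columns for
  sensitivity analysis, but is not the default).

Working in proportion-of-cost units is what makes one model commensurable
across respondents whose monthly costs span $0–$6,000; dollar intervals are
provided only as a reporting convenience (`interval_in_dollars()`), and are
degenerate when the current cost is $0.

The latent WTP fraction follows a linear model with iid normal errors,

$$\mathrm{WTP}_i = x_i'\beta + \varepsilon_i, \qquad
  \varepsilon_i \sim N(0, \sigma^2),$$

so each observation contributes the probability that a normal variate falls
in its censored interval \([l_i, u_i)\):

$$\ell_i(\beta, \sigma) \;=\; \log\!\left[
   \Phi\!\left(\frac{u_i - x_i'\beta}{\sigma}\right)
 - \Phi\!\left(\frac{l_i - x_i'\beta}{\sigma}\right)\right].$$

The normal likelihood is insensitive to whether the interval bounds are
open or closed; the package fixes the closed-lower / open-upper convention,
and the simulator resolves the measure-zero tie "latent WTP exactly equal
to a bid" as a "yes" so that simulation is deterministic given the draws.

## Estimation

`fit_interval_reg()` maximizes \(\sum_i \ell_i\) over \((\beta, \log\sigma)\).
Numerical choices:

* **Parameterization.** The scale enters as \(\log\sigma\), so \(\sigma > 0\)
  on every iterate without constraints.
* **Stable tails.** \(\log[\Phi(b) - \Phi(a)]\) is computed from log-CDFs
  with a log1mexp difference, reflected into the lower tail first, so
  intervals forty standard deviations from the mean still return finite
  log-probabilities instead of underflowing to \(-\infty\).
* **Initializer.** OLS of interval midpoints on the covariates, with
  right-censored observations imputed at their lower bound + 0.05 and
  left-censored at their upper bound − 0.05 (initializer only);
  \(\log\sigma\) starts at the log midpoint-residual SD.  This is cheap and
  scale-aware; no attempt is made to replicate any other package's
  internals.
* **Optimizer.** Newton–Raphson with the analytic score and analytic
  Hessian, step-halving line search, a ridge fallback when the information
  matrix is near-singular, a gradient max-norm tolerance of \(10^{-8}\) (in
  the internally standardized parameterization) and a 200-iteration cap —
  all overridable through `control`.  Covariates are standardized to unit
  SD internally (the dollar-scaled cost covariate would otherwise make the
  information matrix badly conditioned) and everything is mapped back
  afterwards.
* **Degenerate inputs.** A dataset whose intervals are all doubly
  unbounded is rejected as unidentified; rank-deficient designs are
  rejected naming the collinear columns; non-convergence returns the fit
  with `converged = FALSE` and a warning rather than failing silently.

**Robust covariance.**  Reported standard errors come from the sandwich
\(H^{-1}\left(\sum_i s_i s_i'\right) H^{-1}\), with \(s_i\) the
per-observation score at the optimum and \(H\) the observed information.
No small-sample degrees-of-freedom factor is applied by default; the
`dfc` flag enables \(n/(n-k)\) scaling for cross-checking against
implementations that use it.  Under a correctly specified homoskedastic
model the robust and inverse-information SEs agree asymptotically, which
the test suite checks at \(n = 4000\).

**Wald test.**  `wald_test()` tests all slopes jointly (intercept and
\(\log\sigma\) excluded) with the robust covariance block; its size under
the null is verified by simulation (500 replicates at \(n = 2000\), the
rejection rate at \(\alpha = 0.05\) must sit inside binomial 99% bounds).

**Prediction.**  The headline "mean WTP" is the linear prediction at the
estimation-sample covariate means, \(\bar{x}'\hat\beta\), with the
delta-method SE \(\sqrt{\bar{x}' V \bar{x}}\) treating the means as fixed
constants (matching how such tables are conventionally reported); setting
`mean_variance = TRUE` adds the means' own sampling variance for
sensitivity.  Because the model is linear, marginal effects are exact:
`marginal_effect()` returns \(\hat\beta_j \times \delta\), e.g. a
per-dollar cost coefficient of \(-10^{-4}\) scaled by \(\delta = 100\)
gives a one-percentage-point-lower predicted WTP for a $100 higher current
cost.

## Survey-side conventions

* **Skip-logic classification** is a fixed priority, leaser > boarder >
  owner: leasing is the most limited population, so anyone with a leased
  equid is a leaser even if they also own; among non-leasers, any boarded
  equid makes a boarder.  Classification is total on records with at least
  one nonzero count and the three groups partition the classified sample.
* **Covariate coding**: equid-count bins 5–9/10–19/20+ collapse into one
  "5+" indicator (the finer bins stay on the raw record); "South" is the
  16-state Census South; income above $75,000 pools the three top
  brackets; "younger than 35" pools 18–24 and 25–34.  Sex is carried on
  the record but never modeled (insufficient variability).  Free-text
  "other" lease/board descriptions are binned by an ordered, configurable
  keyword-rule table; unresolvable text stays "other" and contributes 0 to
  both the partial and full indicators, i.e. the model baseline.
* **Missing data** are handled by listwise deletion per model (no
  imputation), with per-field drop counts reported — this is what
  separates the descriptive-table sample sizes from the regression sample
  sizes.
* **Descriptives** report the sample SD (n−1); a single observation
  reports SD = 0 with a warning.  Group mean comparisons use the
  pooled-variance Student t-test; the zero-pooled-variance degenerate case
  returns \(t = 0, p = 1\) when means are equal and errors otherwise.
* **Stars** use inclusive thresholds: \(p \le 0.10\) (*), \(\le 0.05\)
  (**), \(\le 0.01\) (***).

## The synthetic generator: what it emulates, and what it does not

Because the original survey's raw respondent data were never deposited,
the package ships a generator (`synthetic_config()`,
`end_to_end_dataset()`) whose defaults — the `"table1-like"` preset —
define the study conditions used throughout the tests:

* **Sample sizes** default to the survey's group sizes (292 owners, 282
  boarders, 79 leasers).
* **Covariate frequencies** are calibrated to the published summary table:
  South 0.73, income > $75k ≈ 0.55 (via the published six-bracket income
  distribution, from which the indicator is derived), age < 35 ≈ 0.33 (via
  the seven-bracket age distribution), pandemic-impact less/more stable
  0.03/0.56, sell/stop intent yes/maybe 0.07/0.09, discipline flags
  0.28/0.10/0.14.  Blocks that are logically exclusive (count bins, board
  and lease types, pandemic impact, intent, brackets) are drawn
  categorically so at most one indicator per block is set; everything else
  is independent Bernoulli.  Board-type shares (free/partial/full/other ≈
  0.05/0.27/0.63/0.05) follow the published per-type counts; lease types
  likewise; 54% of leasers also own (the survey reports 46% leasing only);
  76% of leasers lease a single equid.
* **Costs** are log-normal with parameters solved in closed form from the
  published group mean/SD pairs (owners 406.37/606.40, boarders
  391.42/285.45, leasers 190.22/211.19 USD/month), a point mass at $0 for
  free arrangements, re-drawn above a per-group cap, and rounded to cents.
  A log-normal (not a normal) honors non-negativity and the heavy right
  tail the published moments imply (owner SD > mean).  With truncation and
  the zero mass the *overall* mean sits slightly below the component
  target; the closed-form moment match is exact for the untruncated
  component and is tested there.
* **True parameters** per group are presets, not published estimates: the
  published coefficient table is not reproducible without the raw data, so
  the preset instead echoes the published *response mix* (owners ≈ 71%
  yes-yes, boarders ≈ 66% no-no, leasers ≈ 65% yes-yes) through per-group
  \((\sigma, \text{mean WTP})\) of (0.15, 0.26), (0.08, 0.02), (0.12,
  0.20), with slope magnitudes on the scale of the published columns but
  capped near 0.12.  The cap is an identifiability requirement of the
  design, not a cosmetic choice: the bid ladder only spans 1–20% of
  current cost, so a coefficient large enough to push its subgroup's mean
  far above the top bid (as a published leaser effect of 0.70 would) makes
  that subgroup answer yes-yes almost surely, its likelihood contribution
  flat from above, and the coefficient one-sidedly unidentified — a real
  limitation of double-bounded designs worth keeping in mind when reading
  very large reported coefficients.  Each intercept is derived at
  config-build time so the expected latent mean equals the target given
  the covariate frequencies.
* **Missingness** is MCAR on income (13%), age (11%) and sex (11%),
  emulating the descriptive-to-regression sample-size drop; it is applied
  after the response process, so it cannot distort the latent model.

Deliberate simplifications: covariates are generated independently (the
survey reports no covariate covariances to calibrate a copula to), there
is no nonresponse mechanism beyond MCAR masking, no protest-zero spike,
no survey weighting, and cost is independent of the other covariates.
Passing recovery tests therefore demonstrates that the estimator is
correct *under the model's own assumptions* at realistic sample sizes and
censoring mixes — not that real survey data meet those assumptions.

## What the validation suite establishes

Problem sizes were chosen to make Monte-Carlo error small relative to the
assertion bands: interval mapping is checked exhaustively over all legal
sequence × follow-up combinations; the per-observation likelihood is
checked against a direct normal-CDF oracle on 1000 random configurations
(10⁻¹⁰); intercept-only fits are checked against brute-force grid search
(n = 30 fixtures) and against an independent interval-censored Gaussian
ML implementation (`survival::survreg`); parameter recovery and pooled
95% robust-CI coverage are checked over 200 replicates at 5,000 records
per group; the robust Wald test's size is checked over 500 null
replicates at n = 2,000; and simulated response frequencies are checked
by chi-square goodness of fit (small expected cells merged per Cochran's
rule) against the closed-form sequence probabilities at 20 random
parameter settings.

Coverage is assessed pooled across coefficients: with 200 replicates the
binomial noise on a single coefficient's coverage (±3 percentage points at
2 SD) is wider than the assertion band, so per-coefficient banding would
reject a perfectly calibrated estimator with high probability across ~41
coefficients, while the pooled rate is estimated from ~8,000 intervals.

## Known limitations

* The abstract-level WTP range reported for the original study (18.5% to
  26.2%) does not match its own results table (14.2/15.2/25.6%); the
  package implements only the table's definition — the linear prediction
  at covariate means — and makes no attempt to reconcile the abstract.
* The estimator assumes normal errors; no spike-at-zero, random-effects or
  Bayesian variants are provided.
* Delta-method intervals only (no Krinsky–Robb simulation), matching how
  single SEs are conventionally reported for prediction-at-means.
* The per-dollar cost coefficient is orders of magnitude smaller than the
  indicator coefficients; JSON output therefore never rounds coefficients
  (a table that prints "−0.00" is a display convention, not a value).
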