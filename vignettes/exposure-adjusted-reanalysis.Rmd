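---
title: "Exposure-adjusted reanalysis of a cluster-randomized hand-hygiene trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-adjusted reanalysis of a cluster-randomized hand-hygiene trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handrct)
```

## The scientific problem

Trials of hand-hygiene interventions against acute respiratory (RTI) and
gastrointestinal (GTI) infections are confounded by how much infectious
exposure each participant actually meets: an intervention can only act on
transmission that occurs. `handrct` implements the full analysis chain for
a three-arm, triplet-matched cluster-randomized office trial with weekly
self-reported symptom and exposure diaries: 21 office clusters ranked by a
contagion-risk score, grouped into 7 rank-contiguous triplets, and one
member of each triplet randomized to control, soap-and-water wash, or
alcohol-rub hand hygiene. The analysis endpoint is the *week with reported
symptoms* — a reported week containing at least one symptomatic diary day —
and the key covariate is the self-reported *homologous exposure* ("met a
person with obvious symptoms of the same infection type") during the same
or the preceding week.

Because the original participant-level data were never deposited, the
package ships a first-class synthetic-cohort generator that reproduces the
trial's statistical structure, so every downstream stage is testable
without any external data. The published count tables are embedded
(`reference_counts()`, `reference_rows()`) as worked-example inputs for
the descriptive engine.

## Endpoints and descriptive statistics

`daily_to_weekly()` collapses diary days to the weekly flag;
`episodes_from_daily()` extracts *designated episodes* (maximal runs of
successive symptomatic days, merging across reported week boundaries).
Unreported weeks break episode runs: an episode cannot be asserted through
unobserved days. This is deliberately conservative and matches the
person-week denominators; whether the original analysis merged episodes
across reporting gaps is not documented.

The exposure-conditioned relative risk is implemented as

$$\mathrm{ReR} = \frac{P(\text{symptoms} \mid \text{exposed})}
                      {P(\text{symptoms} \mid \text{unexposed})}$$

at a stated timing (same week, or exposure in the preceding week). The
published verbal formula for ReR ("proportion of weeks with exposure out
of all weeks with symptoms ...") is internally inconsistent with the
published stratified tables and with the published statement that the
same-week control-arm ReR is "more than four-fold"; the conditional-risk
ratio above reproduces both, and is the central interpretive decision of
the descriptives module. The descriptive arm risk ratio RRa divides an
intervention arm's ReR by the control arm's. Proportion intervals are
Jeffreys central 95% intervals — the standard objective-Bayes interval for
a raw proportion, consistent with a credible-interval reading of the
published proportion intervals.

Rows whose preceding calendar week was unreported have an undefined lagged
exposure; they are kept in same-week analyses and dropped from
following-week analyses. The reported site of exposure (work / elsewhere /
both) is carried through descriptively but never modelled.

## The model

For outcome $y_{ijt} \in \{0,1\}$ (symptoms of one outcome type for person
$i$ in cluster $j$, week $t$):

$$\log P(y_{ijt} = 1) = \beta_0 + \beta_{\text{arm}(j)} + \beta_E E_{it}
  + \beta_{\text{arm}(j) \times E} E_{it} + \beta_{\text{month}(t)}
  + u_i + v_j,$$

with $u_i \sim N(0, \sigma_p^2)$, $v_j \sim N(0, \sigma_c^2)$ on the log
scale. The log link makes every coefficient a log risk ratio, at the price
of a bounded support: all fitted probabilities must stay below one.
$E_{it}$ is the reported homologous exposure at the chosen timing; the two
timings are fitted separately (whether the original analysis entered both
simultaneously is ambiguous; a combined fit is deliberately not exposed).
Longitudinal correlation is carried by the person intercept alone — no
autoregressive terms — and the randomization-triplet term is available
(`triplet = TRUE`) but off by default, reflecting the published finding
that matching adjustment was negligible; the package's own sensitivity
test reproduces that negligibility on data simulated without triplet
effects.

### Priors

"Non-informative" is concretized as Normal(0, $10^2$) on every fixed
effect (log scale) and half-normal(2) on both random-effect SDs: proper
but very vague relative to plausible log risk ratios, and compatible with
the bounded log-link support. Doubling the fixed-effect SD moves reported
contrasts by well under half a posterior SD (tested).

### Sampling and diagnostics

The sampler (`fit_prevalence()`, in C++) is an adaptive random-walk
Metropolis-within-Gibbs with four move types per sweep:

* single-site updates of each fixed effect and each random intercept,
  with per-parameter scales adapted toward 44% acceptance;
* repeated joint fixed-effect proposals using a covariance estimated from
  the chain's own burn-in history (scaled $2.38/\sqrt{p}$, 23% target) —
  the intercept, arm, and month effects are strongly correlated and
  single-site moves alone mix them poorly;
* log-scale random walks on $\sigma_p$, $\sigma_c$;
* joint *group-scale* moves rescaling $(u, \sigma_p)$ (and $(v,
  \sigma_c)$) together — a symmetric random walk in $(\log\sigma,
  u/\sigma)$ coordinates. Without this move the centered parameterization
  funnels and the SDs effectively stop mixing.

Proposals putting any observed-pattern probability at or above 1 are
rejected, which is equivalent to truncating the prior to the model's
support. Adaptation runs during burn-in only (first half of each chain);
retained draws are thinned to a bounded store. Chains start from jittered
initial values. Convergence is summarized by split R-hat (computed
in-package) and effective sample size (via `coda`); the fit fails loudly
— error by default, downgradable to a warning — when any reported
parameter has R-hat above 1.05 or ESS below 200. Identical seeds give
identical draws.

### Interaction collapse

Following-week fits include arm-by-exposure interactions; when every
interaction's central 95% credible interval covers zero,
`collapse_interaction()` signals a refit without them, so a single
arm-level risk ratio applies to both exposure strata — mirroring the
published single-estimate treatment of the following-week tables.

## Posterior predictive margins

`margins_set()` standardizes over the pooled reported person-weeks: for
each posterior draw, every row is set to the target arm and exposure
status, months stay as observed, and the random effects are integrated by
drawing a *fresh* person and cluster intercept per row (a "new
individual" margin — a population-prevalence interpretation, rather than
conditioning on the realized intercepts, which the source analysis leaves
unspecified). The per-draw margin is the average of $\exp(\eta)$ with
values at or above 1 truncated to $1 - 10^{-9}$; the truncation rate is
reported, warns above 1%, and aborts in strict mode. All arms share the
same integration noise within a draw, so margin ratios are paired and, in
the no-interaction case, reduce exactly to coefficient contrasts.
Summaries are posterior medians and central 95% intervals — medians
because they are invariant under the ratio transform — plus the posterior
probability that an arm's risk ratio is below one. When a following-week
fit is collapsed, one risk ratio per arm is computed and shared by both
exposure strata, keeping the strata rows exactly identical.

## The synthetic cohort

`sim_params()` houses every generative coefficient on the log-risk scale;
`default_calibration()` is the package's calibrated default. Design
choices:

* **Risk scores** are arbitrary in the source design and unrecoverable;
  they are drawn uniformly and only their ranks matter. Ties break
  lexicographically by cluster id so designs are deterministic.
* **Arm and interaction effects** are derived from the published raw
  exposure-stratum proportions (not from the published model margins,
  which are standardized quantities and do not reproduce the published
  descriptive prevalences when used generatively).
* **Random-intercept SDs** default to $\sigma_p = 0.08$, $\sigma_c =
  0.03$. These look small, but the log-link support constraint — checked
  at construction by maximizing $\eta$ over all covariate patterns with
  both intercepts at $+4$ SD — caps $\sigma_p + \sigma_c$ near 0.14 given
  the calibrated exposure effects (~5x RTI, ~15x GTI). Large shared
  frailty and a near-0.3 exposed weekly risk cannot coexist under a log
  link; this is a structural property of log-binomial models, not a tuning
  convenience.
* **Seasonality** is a cosine on the log scale (winter peak, January
  reference; amplitude 0.25 RTI, 0.15 GTI), roughly matching respiratory
  seasonality in a northern-European office population. Week 1 anchors to
  a configurable Monday (default January 2009) and months are taken from
  each week's Monday.
* **Exposure** is a weekly marked Bernoulli process (per-arm rates from
  the published exposure tables; site distribution from the published
  site breakdown), generated causally prior to same-week symptoms — the
  source discussion notes the same-week direction is ambiguous; a
  generator must pick one. The lagged covariate in generation is the
  previous *reported* week's exposure, false for week 1.
* **Adherence**: each week is reported with probability 0.85 and people
  stop permanently with a geometric dropout time of mean 250 weeks (well
  beyond the 70-week follow-up), giving the "range of variation in
  individual follow-up times" without a specific dropout model.
* RTI and GTI share the person and cluster intercepts but are otherwise
  independent draws: the outcomes are analyzed separately, and shared
  frailty is the minimal structure making both endpoints testable on one
  cohort.
* One root seed drives everything; identical seeds reproduce the record
  list exactly.

What the generator does *not* emulate: contact-network or epidemic
dynamics (exposures are exogenous), the 2009 pandemic period shift,
within-week symptom-day dependence beyond a simple run construction, and
item nonresponse. Passing tests therefore demonstrate correctness of the
analysis machinery under the stated generative structure, not robustness
to every feature of real diary data.

## Experiment sizes and numerical choices

Simulation experiments in the test suite use reduced presets chosen to
exercise the full structure at tractable cost:

* parameter recovery: 20 trials of 7 triplets x 40 weeks x 50
  reporters/cluster (~36,000 person-weeks each), 1,400 MCMC iterations x
  2 chains;
* posterior-probability calibration: 100 null trials of 3 triplets x 20
  weeks x 25 reporters/cluster, 1,200 iterations x 2 chains;
* pipeline structure: 3 triplets x 20 weeks x 30 reporters/cluster,
  1,500 iterations x 2 chains.

The recovery experiment simulates from the same structure the same-week
model fits (lagged exposure channel disabled). With the lagged channel
on, the omitted-covariate factor is independent of the included
covariates, so coefficient *means* are unaffected (the log link is
collapsible over independent factors — verified against an independent
oracle generator), but the replicate-level spread of the realized
exposure contrast grows beyond the model-based posterior SD, and
"recovery of the generating value" stops being a well-posed check. The
lagged channel is exercised by the following-week fits instead.

Other numerical choices: exposure-week ties never arise (exposure is
binary); display rounding is 3 decimal places half-even with full
precision retained internally; the margin support boundary is
$1 - 10^{-9}$; degenerate designs (an unseen arm, a constant exposure
column, a single observed month) are refused or reduced with a warning
rather than silently mis-coded.

## Limitations

* The log-binomial support constraint couples admissible effect sizes and
  random-effect scales; data with both large exposure effects and strong
  clustering cannot be represented, in the generator or the model.
* The MCMC sampler is a random-walk scheme: adequate for the moderate
  dimensionalities here (tens of fixed effects, ~1,000 intercepts) but
  not tuned for much larger cohorts.
* Margins integrate random effects by Monte Carlo; with very small
  standardization populations the integration noise is visible in the
  margin draws (all arms share it, so ratios are less affected).
* The descriptive ReR conditions on *reported* exposure; unrecognized
  exposure remains unadjusted, and over-adjustment attenuation of arm
  effects (both the endpoint and the covariate are proxies) is inherited
  from the design — the package quantifies neither.
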