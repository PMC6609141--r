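---
title: "Methods: trial-based cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

trialcea implements an economic evaluation alongside a cluster-randomised
trial (cRCT) of a school-based alcohol-prevention programme: from raw
pupil-reported service-use questionnaires and a programme cost ledger to
incremental cost-effectiveness estimates, cost-effectiveness planes,
acceptability curves and one-way sensitivity analyses. This vignette is
the package's account of the underlying models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not establish about real data.

## The evaluation problem

A two-arm cRCT randomises ~105 secondary schools 1:1 to a classroom
alcohol-education curriculum plus a brief parental component, or to
education as normal. The binary outcome is heavy episodic drinking (HED)
in the previous 30 days at 33 months — at least 6 units of alcohol in a
single episode for male pupils, 4.5 for female pupils. The economic
question is the cost per pupil experiencing HED *avoided*, from a public
sector perspective (education, health and criminal justice services).

Two cost streams enter the analysis:

* **Public-sector service use**, reported by pupils on a questionnaire
  covering the previous six months, administered at baseline, 12, 24 and
  33 months — so the observed windows are months [−6, 0], [7, 12],
  [19, 24] and [28, 33] relative to baseline, with gaps in between.
  Counts are priced with a 17-service unit-cost ledger at 2013–2014
  prices (`unit_cost_table()`).
* **Programme delivery costs**, a four-component ledger (materials,
  training, classroom teaching, parental-component facilitator) valued at
  opportunity cost; pre-start-up development costs are excluded by
  construction.

## Costing model

### Missing fields versus missing instruments

A blank field on a returned questionnaire means the pupil did not report
using that service, and is costed as **zero use**. A wave is *missing*
only when the entire instrument is absent. A pupil is **cost-complete**
only when all four windows are observed; incomplete pupils keep `NA`
totals and drop out of the complete-case analysis (they can re-enter
through multiple imputation, below).

### Interpolation over the survey gaps

The instrument observes 24 of the 39 months from −6 to 33. Costs in the
gaps are filled by assuming a linear time trend between observation
points. Because the observed windows have equal length but the gaps do
not (6, 6 and 3 months), interpolation is performed on **monthly rates**,
not window totals: each window's cost is divided by 6 and anchored at the
window midpoint (months −3, 9.5, 21.5 and 30.5); the monthly rate for
month *m* ∈ {1..33} is the linear interpolant evaluated at the month
centre *m* − 0.5, with constant extrapolation of the last rate beyond
month 30.5 (only months 31–33 are affected). The pre-baseline window
anchors the left end of the trend — so it *does* shape months 1–6 — but
its own months never enter the totals. Midpoints are the natural
location of a six-month recall total; a linear-trend assumption does
not by itself fix anchor positions, so the midpoint convention is this
package's documented choice. The whole chain is linear in the four
window costs, so it is implemented once as a 33 × 4 weight matrix; the
per-sector decompositions use the same weights and therefore sum to the
pupil total exactly (to floating precision).

### Discounting

Costs in study years 2 and 3 are discounted at 3.5% per annum (the
reference-case rate; 1.5% is available as the public-health sensitivity
rate): months 1–12 undiscounted, 13–24 divided by 1.035, 25–33 by
1.035². Year boundaries are study years indexed from baseline, not
calendar years, because follow-up is indexed from randomisation.
Monetary values are carried at full floating precision; rounding to
whole pounds happens only in report renderers.

## Programme costing

`programme_cost()` aggregates the delivery ledger under three scenarios:
`full` (all components), `no_parental` (drops the facilitator component,
reflecting the very low uptake of the parental element) and
`classroom_only` (stage 1 only — materials and training — assuming no
additional cost of classroom delivery when the curriculum replaces
existing lesson provision). Per-school and per-pupil means use the
denominators that travel with the ledger (105 schools; 5,749 pupils
present at baseline in intervention schools). The report-rounded
per-pupil figure is what `add_programme_cost()` adds to every
intervention-arm pupil; because the shift is constant within arm, the
between-arm cost difference moves by exactly that amount under any
covariate adjustment. National extrapolation multiplies the rounded
per-pupil cost by a cohort count and reports three significant figures,
mirroring how such headline figures are quoted.

## Incremental estimates and uncertainty

Both estimands are arm coefficients of linear models on complete cases:

* **Cost**: total 33-month discounted cost on arm + school location
  (NI/Scotland) + school free-school-meals band (low 0–15.4%, moderate
  15.5–30.4%, high ≥30.5%) + school type (boys/girls/coed) + the pupil's
  pre-baseline window cost, with a school random intercept.
* **Effect**: a linear-probability model of HED at 33 months on arm +
  the same school covariates + baseline drinking, with a school random
  intercept. The arm coefficient *is* the adjusted risk difference; it
  is reported control-minus-intervention so that positive values mean
  cases avoided. A linear-probability model is used precisely because
  the quantity of interest is an adjusted proportion difference, not an
  odds ratio.

Uncertainty comes from a **school-level bootstrap**: schools are the
randomisation and cluster unit, so they are resampled with replacement,
stratified by arm to preserve the observed number of schools per arm.
Both models are refit on each resample jointly, so the replicate pairs
(Δc, Δe) preserve the cost–effect correlation; intervals are the 2.5th
and 97.5th percentiles of 1,000 replicates (percentile intervals — the
plainest choice absent any reason for bias correction). Point estimates
always come from the mixed models. Replicate refits default to the
fixed-effects (OLS / linear-probability) versions of the same models:
the school resampling itself carries the cluster structure, the arm
contrast is the same estimand, and refitting two mixed models per
resample is an order of magnitude slower for no inferential gain at
B = 1000; `engine = "lmer"` refits the random-intercept models per
replicate for users who want it. If a mixed-model point fit fails, the
fixed-effects fit is used with a warning; a bootstrap replicate whose
resampled design turns degenerate (e.g. a covariate stratum vanishing)
is redrawn, up to a capped number of retries.

Covariates that do not vary in a given dataset (or resample) are dropped
from the formula automatically — a single-level factor would otherwise
abort the fit rather than contribute nothing.

## Decision outputs

`classify_dominance()` applies the conventional rules: in the south-east
quadrant of the CE plane (cheaper, more effective) the intervention
dominates, downgraded to *weak* dominance when either 95% interval spans
zero; north-west is dominated; north-east and south-west are trade-offs
with ICER = Δc/Δe. A negative ICER (numerator and denominator of
opposite sign) carries no meaning and is suppressed, as is the ICER when
Δe = 0.

`ceac()` computes, for each willingness-to-pay threshold λ (pounds per
HED case avoided), the proportion of replicates with positive net
monetary benefit λ·Δe − Δc. Two tie rules are fixed and shared across
operations: acceptability uses the **strict** inequality (NMB exactly
zero counts as not cost-effective), and plane quadrants assign Δc = 0 to
the southern side, Δe = 0 to the western side. Both rules are arbitrary
on sets of probability zero for continuous replicates; fixing them makes
the enumeration tests exact. The default λ grid is £0–£2,000 in £5
steps, spanning the range over which such programmes are judged (the
per-pupil programme cost itself, £15, is the natural reference
threshold).

## Sensitivity analyses

* **Multiple imputation** (`impute_mice()`): missing totals and outcomes
  are filled by chained equations — predictive mean matching (five
  donors, proper posterior draws of the regression parameters) for cost
  variables, a logistic draw for binary ones — cycling 10 times per
  imputation, m = 5 imputations by default, pooled by Rubin's rules
  (`pool_rubin()`: mean of estimates; within-variance plus (1 + 1/m) ×
  between-variance; t interval with the classical Rubin degrees of
  freedom). Predictors are the arm, baseline cost and drinking, the
  school strata, and the other imputation targets, including the interim
  (12-month) cost window and drinking indicator as auxiliaries. The
  donor count and cycle count default to the conventional 5 and 10. The implementation is in-package
  (no imputation dependency); PMM guarantees imputed costs are observed
  donor values, which the tests assert. School membership enters through
  the school-level strata rather than ~100 school dummies; with five
  imputations the coarser clustering proxy is a deliberate
  simplification.
* **Discounting at 1.5%**: the costing chain is re-run at the lower
  rate, and the effect estimate is divided by 1.015² (the outcome is
  realised in study year 3). The primary analysis discounts costs only;
  discounting the outcome as well is confined to this variant, which is
  framed as discounting costs *and* outcomes at the lower rate.
* **Cluster-only adjustment**: both models drop the baseline covariates
  but keep the school-level structure.
* **±5% costs**: every pupil's total cost (programme cost included) is
  multiplied by 1.05 / 0.95 before modelling, probing the linear-trend
  assumption in the interpolation. By construction Δc scales exactly and
  the effect side is untouched — asserted as an exact test.

## The synthetic-data generator

No pupil-level data from the motivating trial are deposited, so the
package ships a generator (`simulate_trial()`) whose defaults *are* the
study conditions, and every pipeline stage is validated against its
known truth:

* **Design**: 105 schools (~108 pupils each, negative-binomial sizes),
  1:1 school-level allocation, two-thirds of schools in Northern
  Ireland, FSM bands drawn uniformly over the three bands, school types
  15/15/70% boys/girls/coed.
* **Costs are induced through service counts**, not drawn directly:
  per-service zero-inflated negative-binomial counts per wave
  (`default_service_rates()`), priced through the same costing chain as
  real data — so the item-missing zero rule, interpolation and
  discounting are all exercised. Rate defaults are plausibility choices
  targeting an order-of-magnitude-realistic 33-month public-sector cost
  (~£2,300, health-dominated); no pupil-level distributions exist to
  copy. Service use drifts up 5% per wave as pupils age.
* **The true incremental cost** (default −£30 on the discounted
  33-month scale) is embedded by scaling intervention-arm post-baseline
  rates by a factor solved from the interpolation/discount weights, so
  the generator's truth is exact in expectation whatever the rate
  configuration.
* **Outcome**: school random intercepts on the logit scale with the
  intercept solved by numerical integration so the *marginal* arm
  prevalences hit the configured 0.23 / 0.15 — a true effect of 0.08
  cases avoided — with baseline drinkers (prevalence 0.05) at 3× odds.
  The latent-logistic translation σ² = ICC·π²/3 ÷ (1 − ICC) maps the
  outcome ICC (default 0.04); the cost ICC (default 0.02) maps to a
  lognormal school multiplier via the marginal mean and an analytic
  count-variance approximation evaluated at multiplier one. A pupil-level
  lognormal frailty (log-SD 0.5) adds the between-pupil overdispersion
  real cost data show. An optional `outcome_mode = "units"` draws a
  worst-episode units measure and derives HED from the sex-specific
  6 / 4.5-unit thresholds; the default draws the binary outcome directly.
* **Missingness** is applied per instrument. The default mechanism is
  MNAR: the logit of wave missingness loads on high-FSM schools (odds
  ×1.5), baseline drinking (×1.8) and the pupil's latent cost propensity
  (×1.6 per SD), so incomplete pupils are heavier service users — the
  direction reported for the real trial — and base probabilities are set
  so that roughly two-thirds of pupils end up complete. MAR drops the
  cost-propensity term; MCAR keeps only the base rate. One consequence,
  visible in the package's own validation, is that complete-case
  estimates of the effect are very slightly attenuated relative to the
  configured truth under the MNAR default — exactly the complete-case
  fragility the sensitivity analyses are for; under MCAR the attenuation
  vanishes.

What passing tests on generated data do **not** show: the generator
draws independent waves given school and pupil effects (no serial
correlation in service use), keeps baseline drinking always observed,
uses a stylised school-size and FSM distribution, and embeds a
multiplicative, constant intervention effect on costs. Agreement of the
pipeline with the generator's truth validates the estimation machinery,
not the behavioural realism of any particular dataset.

## Validation problem sizes

The package's acceptance checks run, by its own choice of scale: exact
ledger arithmetic (instant); 200 replications of a 20-school × ~30-pupil
trial with B = 200 bootstrap resamples for parameter recovery and CI
coverage (a few minutes); and one full-scale run (105 schools, ~11,000
pupils, B = 1000) to demonstrate the runtime envelope. Percentile
intervals with 10 clusters per arm sit at the edge of where cluster
bootstraps are trustworthy; coverage is checked against a binomial error
band around 0.95 rather than asserted exact.

## Known limitations

* Stata's mixed-model numerics are not reproduced bit-for-bit; agreement
  with any external implementation is statistical, not numerical.
* The effect model is a linear probability model; predicted pupil-level
  probabilities outside [0, 1] are possible (harmless for the adjusted
  risk difference, which is the only quantity used).
* The MI variant pools model-based variances; it does not bootstrap
  within imputations, so its interval is normal-theory rather than
  percentile.
* Unit costs are consumed as data at 2013–2014 prices; re-basing to
  other price years is out of scope.
* With very small cluster counts the percentile bootstrap can
  undercover; users designing small trials should widen B and treat the
  intervals cautiously.
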