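# trialcea

Economic evaluation alongside cluster-randomised trials of school-based
prevention programmes, as a reusable, tested R pipeline. `trialcea`
takes pupil-reported public-sector service use (education, health and
criminal justice contacts), a unit-cost ledger and a programme delivery
cost ledger, and produces covariate-adjusted incremental costs and
effects with cluster-bootstrap uncertainty, cost-effectiveness planes,
acceptability curves (CEACs), dominance classifications and one-way
sensitivity analyses — plus a synthetic cluster-RCT generator with known
ground truth so the whole chain can be validated end to end.

## The analysis in brief

A two-arm trial randomises schools 1:1 to an alcohol-education
intervention or education as normal. The effect measure is the
proportion of pupils experiencing a heavy episodic drinking (HED) case
*avoided* at 33 months (Δe, positive favouring the intervention); the
cost measure is the between-arm difference in 33-month discounted
public-sector cost plus the per-pupil programme cost (Δc, in pounds).

* **Costing.** Service-use counts from four six-month recall windows
  (months −6–0, 7–12, 19–24, 28–33) are priced with a 17-service
  unit-cost table (2013–2014 prices). Blank questionnaire fields count
  as zero use; a pupil missing any entire window is cost-incomplete.
  Gaps between windows are filled by linear interpolation of monthly
  cost rates anchored at window midpoints; year-2 and year-3 costs are
  discounted at 3.5% per annum. The pre-baseline window anchors the
  interpolation but never enters totals.
* **Inference.** Δc and Δe are arm coefficients of mixed models with a
  school random intercept, adjusted for school location, free-school-
  meals band, school type, and baseline cost (cost model) or baseline
  drinking (effect model; a linear-probability model so the coefficient
  is the adjusted risk difference). Uncertainty: schools are resampled
  with replacement, stratified by arm, both models refit per resample
  (B = 1000), and 95% intervals are the percentile bounds of the
  replicate pairs, which preserve the cost–effect correlation.
* **Decisions.** The ICER Δc/Δe is reported only in the trade-off
  quadrants; a negative ICER carries no meaning and is suppressed.
  Cheaper-and-more-effective is dominance, downgraded to *weak*
  dominance when a confidence interval spans zero. The CEAC reports, at
  each willingness-to-pay λ, the fraction of replicates with positive
  net monetary benefit λ·Δe − Δc.
* **Sensitivity.** Multiple imputation by chained equations (PMM for
  costs, logit for the outcome, Rubin's rules, m = 5), discounting at
  1.5%, cluster-only adjustment, and ±5% total-cost perturbations.

See `vignette("trial-cea-methods")` for the full model account and the
package's design choices.

## Worked example

Programme costing from the shipped delivery ledger:

```r
library(trialcea)
programme_cost()
#> # A tibble: 1 × 6
#>   scenario stage1_subtotal stage2_subtotal total per_school per_pupil
#>   <chr>              <dbl>           <dbl> <dbl>      <dbl>     <dbl>
#> 1 full               44773           41127 85900       818.      14.9
```

£85,900 in total — £818 per school, £15 per pupil once rounded for
reporting; `scenario = "no_parental"` (£692/£13) and
`scenario = "classroom_only"` (£426/£8) price the delivery variants, and
`extrapolate_cost(15, 685300)` gives the £10.3M national figure.

A simulated trial through the full chain (30 schools here to keep the
example quick; the generator's truth is Δc = −£30 in service costs —
so −£15 after the £15 programme cost — and Δe = 0.08):

```r
sim <- simulate_trial(trial_config(n_schools = 30, pupils_per_school = 60),
                      seed = 1)
dat <- analysis_dataset(sim) |>
  add_programme_cost(round(programme_cost()$per_pupil))
cc  <- dplyr::filter(dat, complete)   # 1221 of 1817 pupils cost+outcome complete
est <- cluster_bootstrap(cc, B = 1000, seed = 1)
est
#> <incremental_estimates>
#>   incremental cost  : 140.22 (-112.43, 388.23)
#>   cases avoided     : 0.10 (0.05, 0.16)
#>   1000 bootstrap resamples of 30 schools (seed 1), adjusted

classify_dominance(est$delta_c, est$delta_e, est$ci_c, est$ci_e)
#> # A tibble: 1 × 3
#>   quadrant label      icer
#>   <chr>    <chr>     <dbl>
#> 1 NE       trade_off 1406.

dplyr::filter(ceac(est), lambda %in% c(0, 15, 800, 2000))
#> # A tibble: 4 × 2
#>   lambda probability
#>    <dbl>       <dbl>
#> 1      0       0.162
#> 2     15       0.163
#> 3    800       0.377
#> 4   2000       0.702
```

Reading this: the effect estimate (0.10 cases avoided, CI excluding
zero) is close to the generated truth of 0.08, while the cost estimate
is noisy at 30 schools — the point estimate lands in the north-east
quadrant, so an ICER (£1,406 per case avoided) is reported, and the wide
cost interval comfortably covers the true −£15. The CEAC turns that
uncertainty into the probability the intervention is cost-effective at
each willingness to pay. At the full 105-school design
(`trial_config()` defaults) the cost interval tightens accordingly.
`plot_ce_plane(est)` and `plot_ceac(ceac(est))` (or `autoplot()`) draw
the standard figures; `run_pipeline()` orchestrates every stage and
writes `costs.csv`, `estimates.json`, `ceac.csv`, `plane.csv` and a run
manifest; `run_sensitivity()` produces the sensitivity-analysis table.
A thin command-line front end with the same stages lives at
`inst/scripts/trialcea` (subcommands `simulate`, `cost`, `analyze`,
`ceac`, `sensitivity`, `report`, `all`).

## File formats

* `unit_costs.csv` — `service_id,label,sector,unit_cost`; shipped
  defaults in `inst/extdata/`.
* `programme_costs.csv` — `stage,component,label,amount`.
* `service_use.csv` — long format `pupil_id,wave,service_id,count`
  with waves `pre_baseline`, `m7_12`, `m19_24`, `m28_33`. An empty
  `count` cell is an item-missing field (costed as zero use); a
  (pupil, wave) with no rows is a missing instrument, which can be made
  explicit with a `pupil_waves.csv` flag file
  (`pupil_id,wave,wave_missing`).

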