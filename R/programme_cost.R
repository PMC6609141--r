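# Programme (intervention) costing: aggregate the delivery-cost ledger under
# alternative delivery scenarios, extrapolate nationally, and attach the
# per-pupil programme cost to the analysis dataset.

#' Aggregate the programme cost ledger
#'
#' Sums the delivery ledger into stage subtotals, a total, and per-school /
#' per-pupil means, under one of three delivery scenarios:
#' \describe{
#'   \item{`full`}{all components.}
#'   \item{`no_parental`}{drops the facilitator component (the parental
#'     element, which saw very low uptake).}
#'   \item{`classroom_only`}{stage 1 only (materials and training): assumes
#'     no additional cost of classroom delivery when the curriculum is
#'     folded into existing lesson provision.}
#' }
#' Per-pupil and per-school figures are returned at full floating
#' precision; rounding to whole pounds happens only at report time (see
#' [render_table_programme()]).
#'
#' @param ledger Programme cost ledger; defaults to [programme_ledger()].
#'   Must have columns `stage`, `component`, `label`, `amount`.
#' @param scenario One of `"full"`, `"no_parental"`, `"classroom_only"`.
#' @param n_schools,n_pupils Denominators for the per-school and per-pupil
#'   means; default to the ledger's attributes (105 schools; 5 749 pupils
#'   present at baseline in intervention schools).
#' @return A one-row tibble: `scenario`, `stage1_subtotal`,
#'   `stage2_subtotal`, `total`, `per_school`, `per_pupil` (pounds).
#' @examples
#' programme_cost() # total 85 900; ~818/school; ~15/pupil
#' programme_cost(scenario = "no_parental")
#' @export
programme_cost <- function(ledger = programme_ledger(),
                           scenario = c("full", "no_parental", "classroom_only"),
                           n_schools = attr(ledger, "n_schools"),
                           n_pupils = attr(ledger, "n_pupils")) {
  scenario <- match.arg(scenario)
  ledger <- as_tibble(ledger)
  if (nrow(ledger) > 0) {
    assert_columns(ledger, c("stage", "component", "amount"), "programme ledger")
    if (any(ledger$amount < 0)) abort("ledger amounts must be non-negative")
  }
  if (is.null(n_schools) || is.null(n_pupils) ||
      n_schools <= 0 || n_pupils <= 0) {
    abort("n_schools and n_pupils must be positive counts")
  }

  kept <- switch(scenario,
    full = ledger,
    no_parental = filter(ledger, .data$component != "facilitator"),
    classroom_only = filter(ledger, .data$stage == 1L)
  )
  s1 <- sum(kept$amount[kept$stage == 1L])
  s2 <- sum(kept$amount[kept$stage == 2L])
  total <- s1 + s2
  tibble(
    scenario = scenario,
    stage1_subtotal = s1,
    stage2_subtotal = s2,
    total = total,
    per_school = total / n_schools,
    per_pupil = total / n_pupils
  )
}

#' Extrapolate a per-pupil cost to a national cohort
#'
#' Multiplies a per-pupil programme cost by a population count and reports
#' the product to three significant figures (the convention used for
#' headline national totals).
#'
#' @param per_pupil Per-pupil cost in pounds (use the report-rounded figure
#'   when mirroring headline arithmetic).
#' @param population Number of pupils in the target cohort (e.g. 685 300
#'   12-year-olds in the UK, 2013/2014).
#' @return The extrapolated total in pounds, to 3 significant figures.
#' @examples
#' extrapolate_cost(15, 685300) # 10 300 000
#' @export
extrapolate_cost <- function(per_pupil, population) {
  if (any(per_pupil < 0)) abort("per_pupil must be non-negative")
  signif(per_pupil * population, 3)
}

#' Add the per-pupil programme cost to the intervention arm
#'
#' Increments `total_cost` by the per-pupil programme cost for every pupil
#' in the intervention arm, leaving the control arm unchanged. Because the
#' shift is a constant within arm, the between-arm cost difference moves by
#' exactly `per_pupil` under any covariate-adjustment model (constant-shift
#' equivariance).
#'
#' @param data Analysis data frame with columns `arm` and `total_cost`.
#' @param per_pupil Per-pupil programme cost in pounds.
#' @return The data with `total_cost` shifted in the intervention arm.
#' @export
add_programme_cost <- function(data, per_pupil) {
  assert_columns(data, c("arm", "total_cost"), "analysis data")
  mutate(
    as_tibble(data),
    total_cost = .data$total_cost +
      per_pupil * (as.character(.data$arm) == "intervention")
  )
}
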