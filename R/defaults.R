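# Shipped reference tables: the public-sector unit-cost ledger (2013-2014
# prices) and the programme delivery-cost ledger, plus the survey-wave
# calendar used throughout the costing module.

#' Public-sector unit costs (2013-2014 prices)
#'
#' The default unit-cost ledger for the service-use questionnaire: 17
#' public-sector services partitioned into education (5), health (10) and
#' criminal justice (2), each priced in pounds per contact, visit, stay or
#' call at 2013-2014 prices. The ledger is data, not logic: re-basing to
#' another price year is out of scope, but any table with the same columns
#' can be passed to the costing functions.
#'
#' @return A tibble with columns `service_id`, `label`, `sector`
#'   (`"education"`, `"health"` or `"criminal_justice"`) and `unit_cost`
#'   (pounds per unit of use).
#' @examples
#' unit_cost_table()
#' @export
unit_cost_table <- function() {
  tbl <- tibble::tribble(
    ~service_id,                 ~label,                                                    ~sector,            ~unit_cost,
    "school_nurse",              "School nurse",                                            "education",        50.00,
    "school_counsellor",         "School counsellor/guidance teacher",                      "education",        35.02,
    "intervention_teacher",      "Intervention teacher",                                    "education",        25.89,
    "educational_psychologist",  "Educational psychologist",                                "education",        41.00,
    "education_welfare_officer", "Education welfare officer/home school liaison officer",   "education",        27.00,
    "gp_surgery",                "GP surgery visit",                                        "health",           46.00,
    "gp_out_of_hours",           "GP out of hours",                                         "health",           115.00,
    "nurse_other",               "Nurse (other than school nurse)",                         "health",           13.70,
    "hospital_appointment",      "Hospital appointment",                                    "health",           109.00,
    "accident_emergency",        "Accident and emergency",                                  "health",           233.00,
    "overnight_stay",            "Overnight hospital stay",                                 "health",           658.33,
    "psychologist",              "Psychologist",                                            "health",           50.00,
    "counsellor_other",          "Counsellor (other than at school)",                       "health",           50.00,
    "social_worker",             "Social worker",                                           "health",           79.00,
    "telephone_helpline",        "Telephone help-line",                                     "health",           3.99,
    "youth_justice",             "Youth justice service",                                   "criminal_justice", 84.00,
    "police",                    "Police service",                                          "criminal_justice", 325.00
  )
  validate_unit_costs(tbl)
}

#' Validate a unit-cost table
#'
#' Checks the structural invariants any unit-cost ledger must satisfy:
#' required columns, unique service ids, recognised sectors and strictly
#' positive unit costs.
#'
#' @param table A data frame with columns `service_id`, `label`, `sector`,
#'   `unit_cost`.
#' @return The table, invisibly coerced to a tibble, if valid; otherwise an
#'   error.
#' @export
validate_unit_costs <- function(table) {
  table <- as_tibble(table)
  assert_columns(table, c("service_id", "label", "sector", "unit_cost"),
                 "unit-cost table")
  if (anyDuplicated(table$service_id)) {
    abort("unit-cost table has duplicated service_id values")
  }
  bad_sector <- setdiff(
    unique(table$sector),
    c("education", "health", "criminal_justice")
  )
  if (length(bad_sector) > 0) {
    abort(sprintf("unknown sector(s): %s", paste(bad_sector, collapse = ", ")))
  }
  if (any(!is.finite(table$unit_cost) | table$unit_cost <= 0)) {
    abort("every unit_cost must be a finite positive number")
  }
  table
}

#' Programme delivery-cost ledger
#'
#' The default intervention cost ledger: four components split into stage 1
#' (planning and preparation: materials, training) and stage 2 (delivery:
#' classroom teaching, facilitator for the parental component). Pre-start-up
#' development costs are excluded by construction; there is no ledger slot
#' for them. Denominators travel with the ledger as attributes:
#' 105 schools, 5 749 pupils present at baseline in intervention schools,
#' and 192 classes.
#'
#' @return A tibble with columns `stage` (1 or 2), `component`, `label` and
#'   `amount` (pounds), carrying attributes `n_schools`, `n_pupils` and
#'   `n_classes`.
#' @examples
#' programme_ledger()
#' @export
programme_ledger <- function() {
  tbl <- tibble::tribble(
    ~stage, ~component,    ~label,                                ~amount,
    1L,     "materials",   "Materials",                           6694,
    1L,     "training",    "Training",                            38079,
    2L,     "teaching",    "Teaching",                            27877,
    2L,     "facilitator", "Facilitator (for parental component)", 13250
  )
  attr(tbl, "n_schools") <- 105L
  attr(tbl, "n_pupils") <- 5749L
  attr(tbl, "n_classes") <- 192L
  tbl
}

# Survey-wave calendar ---------------------------------------------------------

#' Survey waves of the service-use instrument
#'
#' The instrument covers the previous six months at each administration,
#' yielding four observation windows in months relative to baseline:
#' `pre_baseline` \[-6, 0\], `m7_12` \[7, 12\], `m19_24` \[19, 24\] and
#' `m28_33` \[28, 33\]. The pre-baseline window anchors the interpolation
#' but never contributes to totals. Window midpoints (-3, 9.5, 21.5, 30.5)
#' are where each window's monthly rate is anchored.
#'
#' @return A tibble with columns `wave`, `start`, `end`, `midpoint` (months
#'   relative to baseline).
#' @export
wave_calendar <- function() {
  tibble(
    wave = wave_levels(),
    start = c(-6, 7, 19, 28),
    end = c(0, 12, 24, 33),
    midpoint = c(-3, 9.5, 21.5, 30.5)
  )
}

wave_levels <- function() c("pre_baseline", "m7_12", "m19_24", "m28_33")

wave_midpoints <- function() c(-3, 9.5, 21.5, 30.5)

#' Band a school's free-school-meals percentage
#'
#' Deprivation proxy bands on the percentage of pupils entitled to free
#' school meals: low 0--15.4, moderate 15.5--30.4, high 30.5 and above.
#'
#' @param fsm_pct Numeric vector of percentages in \[0, 100\].
#' @return A factor with levels `low`, `moderate`, `high`.
#' @examples
#' fsm_band(c(3, 15.4, 15.5, 30.4, 30.5, 62))
#' @export
fsm_band <- function(fsm_pct) {
  if (any(fsm_pct < 0 | fsm_pct > 100, na.rm = TRUE)) {
    abort("fsm_pct must be a percentage in [0, 100]")
  }
  cut(
    fsm_pct,
    breaks = c(-Inf, 15.45, 30.45, Inf),
    labels = c("low", "moderate", "high"),
    right = FALSE
  )
}
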