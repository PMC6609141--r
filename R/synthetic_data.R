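# Synthetic cluster-RCT generator.
#
# Emulates a two-arm school-randomised trial with four six-month
# service-use windows, overdispersed zero-inflated service counts, a
# binary heavy-episodic-drinking (HED) outcome at 33 months, school-level
# random effects matched to target intraclass correlations, and
# non-random wave missingness. Costs are induced through service *counts*
# (priced later by the costing module), so every downstream stage --
# including the item-missing zero rule and the interpolation -- is
# exercised on generated data. The returned truth object carries the
# design parameters (true incremental cost and effect, ICCs) for recovery
# testing.

#' Default per-service usage rates
#'
#' Per-service zero-inflation probability, marginal mean count per
#' six-month window and negative-binomial dispersion used by the
#' generator. Values are plausibility choices for a school-age cohort
#' (most pupils use no services in a window; health contacts dominate
#' costs), set for order-of-magnitude realism of the implied 33-month
#' public-sector cost (~GBP 2,300, health-dominated), since no pupil-level
#' distributions are available to copy.
#'
#' @return A tibble: `service_id`, `zero_prob`, `mean_count`, `size`.
#' @export
default_service_rates <- function() {
  tibble::tribble(
    ~service_id,                 ~zero_prob, ~mean_count, ~size,
    "school_nurse",              0.75,       0.50,        1,
    "school_counsellor",         0.85,       0.30,        1,
    "intervention_teacher",      0.85,       0.30,        1,
    "educational_psychologist",  0.95,       0.10,        1,
    "education_welfare_officer", 0.93,       0.15,        1,
    "gp_surgery",                0.60,       0.55,        1,
    "gp_out_of_hours",           0.94,       0.06,        1,
    "nurse_other",               0.85,       0.30,        1,
    "hospital_appointment",      0.75,       0.35,        1,
    "accident_emergency",        0.80,       0.25,        1,
    "overnight_stay",            0.82,       0.28,        1,
    "psychologist",              0.94,       0.08,        1,
    "counsellor_other",          0.94,       0.08,        1,
    "social_worker",             0.93,       0.10,        1,
    "telephone_helpline",        0.80,       0.30,        1,
    "youth_justice",             0.95,       0.08,        1,
    "police",                    0.96,       0.045,       1
  )
}

#' Wave-missingness settings
#'
#' Missingness is applied at the instrument (wave) level; an absent
#' instrument removes all of that wave's counts. The mechanism controls
#' which terms enter the missingness model on the logit scale:
#' `MCAR` uses the base probability only; `MAR` adds odds multipliers for
#' attending a high-FSM school and for baseline drinking; `MNAR`
#' (default) additionally loads on the pupil's latent cost propensity, so
#' heavier service users are more likely to be incomplete -- the direction
#' observed in practice. The 33-month outcome response is modelled the
#' same way with its own base probability.
#'
#' @param mechanism `"MNAR"`, `"MAR"` or `"MCAR"`.
#' @param wave_missing_base_prob Per-wave missingness probability for a
#'   reference pupil (low/moderate-FSM school, no baseline drinking,
#'   average cost propensity).
#' @param outcome_missing_base_prob As above for the 33-month outcome item.
#' @param or_fsm_high Odds multiplier for pupils in high-FSM schools.
#' @param or_baseline_hed Odds multiplier for baseline drinkers.
#' @param or_mnar_per_sd Odds multiplier per SD of latent cost propensity
#'   (MNAR only).
#' @return A list of class `missingness_config`.
#' @export
missingness_config <- function(mechanism = c("MNAR", "MAR", "MCAR"),
                               wave_missing_base_prob = 0.062,
                               outcome_missing_base_prob = 0.045,
                               or_fsm_high = 1.5,
                               or_baseline_hed = 1.8,
                               or_mnar_per_sd = 1.6) {
  mechanism <- match.arg(mechanism)
  stopifnot(
    wave_missing_base_prob >= 0, wave_missing_base_prob <= 1,
    outcome_missing_base_prob >= 0, outcome_missing_base_prob <= 1,
    or_fsm_high > 0, or_baseline_hed > 0, or_mnar_per_sd > 0
  )
  structure(
    list(
      mechanism = mechanism,
      wave_missing_base_prob = wave_missing_base_prob,
      outcome_missing_base_prob = outcome_missing_base_prob,
      or_fsm_high = or_fsm_high,
      or_baseline_hed = or_baseline_hed,
      or_mnar_per_sd = or_mnar_per_sd
    ),
    class = "missingness_config"
  )
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic trial. Defaults emulate the study
#' conditions the pipeline targets: 105 schools of ~108 pupils randomised
#' 1:1, two-thirds of schools in Northern Ireland, a true incremental
#' (discounted, 33-month) service cost of -GBP 30 in the intervention arm,
#' 33-month HED prevalences of 0.23 (control) vs 0.15 (intervention) --
#' i.e. a true effect of 0.08 cases avoided -- and wave missingness
#' leaving roughly two-thirds of pupils complete.
#'
#' @param n_schools Number of schools (clusters), randomised 1:1.
#' @param pupils_per_school Mean school cohort size.
#' @param pupil_dispersion Negative-binomial size for cohort sizes.
#' @param location_split Probability a school is in Northern Ireland
#'   (vs Scotland).
#' @param fsm_probs Probabilities of the low/moderate/high FSM bands.
#' @param school_type_probs Probabilities of boys/girls/coed schools.
#' @param service_rates Per-service rate table, see
#'   [default_service_rates()].
#' @param cost_trend Multiplicative drift of service use across the four
#'   waves (service use rises as pupils age).
#' @param true_delta_cost True between-arm difference in the discounted
#'   33-month service cost (pounds; negative = saving). Embedded by
#'   scaling intervention-arm post-baseline service rates.
#' @param control_hed_prev,intervention_hed_prev Marginal 33-month HED
#'   prevalences by arm; their difference is the generator's true effect.
#' @param baseline_hed_prev Baseline drinking prevalence.
#' @param baseline_hed_or Odds multiplier on 33-month HED for baseline
#'   drinkers.
#' @param hed12_prev Approximate prevalence of the interim (12-month)
#'   drinking indicator used as an imputation auxiliary.
#' @param icc_cost,icc_outcome Target school-level intraclass
#'   correlations of the 33-month cost and the outcome (latent scale).
#' @param sigma_pupil_cost Log-scale SD of the pupil-level cost frailty
#'   (between-pupil overdispersion shared across waves; also the handle
#'   the MNAR mechanism loads on).
#' @param item_missing_prob Probability an individual questionnaire field
#'   is left blank within an otherwise returned instrument (costed as
#'   zero use downstream).
#' @param missingness A [missingness_config()].
#' @param outcome_mode `"prevalence"` (default) draws the binary HED
#'   outcome directly from the arm prevalences; `"units"` draws a
#'   worst-episode units-of-alcohol measure per pupil and derives HED from
#'   the sex-specific thresholds (>= 6 units male, >= 4.5 female).
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_schools = 105,
                         pupils_per_school = 108,
                         pupil_dispersion = 25,
                         location_split = 0.67,
                         fsm_probs = c(low = 1 / 3, moderate = 1 / 3, high = 1 / 3),
                         school_type_probs = c(boys = 0.15, girls = 0.15, coed = 0.70),
                         service_rates = default_service_rates(),
                         cost_trend = c(1, 1.05, 1.10, 1.15),
                         true_delta_cost = -30,
                         control_hed_prev = 0.23,
                         intervention_hed_prev = 0.15,
                         baseline_hed_prev = 0.05,
                         baseline_hed_or = 3,
                         hed12_prev = 0.10,
                         icc_cost = 0.02,
                         icc_outcome = 0.04,
                         sigma_pupil_cost = 0.5,
                         item_missing_prob = 0.02,
                         missingness = missingness_config(),
                         outcome_mode = c("prevalence", "units")) {
  outcome_mode <- match.arg(outcome_mode)
  probs <- c(
    location_split, fsm_probs, school_type_probs,
    control_hed_prev, intervention_hed_prev, baseline_hed_prev, hed12_prev,
    item_missing_prob
  )
  if (any(probs < 0 | probs > 1)) {
    abort("infeasible config: all probabilities must lie in [0, 1]")
  }
  if (abs(sum(fsm_probs) - 1) > 1e-8 || abs(sum(school_type_probs) - 1) > 1e-8) {
    abort("infeasible config: fsm_probs and school_type_probs must sum to 1")
  }
  if (icc_cost < 0 || icc_cost >= 1 || icc_outcome < 0 || icc_outcome >= 1) {
    abort("infeasible config: ICCs must lie in [0, 1)")
  }
  if (n_schools < 4) abort("infeasible config: need at least 4 schools")
  if (length(cost_trend) != 4 || any(cost_trend <= 0)) {
    abort("infeasible config: cost_trend must be 4 positive multipliers")
  }
  structure(
    list(
      n_schools = n_schools, pupils_per_school = pupils_per_school,
      pupil_dispersion = pupil_dispersion, location_split = location_split,
      fsm_probs = fsm_probs, school_type_probs = school_type_probs,
      service_rates = as_tibble(service_rates), cost_trend = cost_trend,
      true_delta_cost = true_delta_cost,
      control_hed_prev = control_hed_prev,
      intervention_hed_prev = intervention_hed_prev,
      baseline_hed_prev = baseline_hed_prev,
      baseline_hed_or = baseline_hed_or,
      hed12_prev = hed12_prev,
      icc_cost = icc_cost, icc_outcome = icc_outcome,
      sigma_pupil_cost = sigma_pupil_cost,
      item_missing_prob = item_missing_prob,
      missingness = missingness, outcome_mode = outcome_mode
    ),
    class = "trial_config"
  )
}

# --- ICC translations ---------------------------------------------------------

# Latent-logistic translation for the binary outcome:
# icc = sigma^2 / (sigma^2 + pi^2 / 3).
icc_to_sigma_outcome <- function(icc) {
  sqrt(icc * (pi^2 / 3) / (1 - icc))
}

# Lognormal-multiplier translation for costs. With a school multiplier
# exp(u), u ~ N(-s^2/2, s^2), the between-school variance of the expected
# pupil total is M^2 (exp(s^2) - 1) where M is the marginal mean total.
# The within-school variance is approximated at multiplier 1 as the pupil
# frailty term plus the count-level (zero-inflated NB) variance, both
# propagated through the linear interpolation/discount weights.
icc_to_sigma_cost <- function(config, unit_costs, discount_rate = 0.035) {
  sr <- left_join(config$service_rates, unit_costs, by = "service_id")
  keep <- 1 - config$item_missing_prob
  w <- window_total_weights(discount_rate)
  sp2 <- config$sigma_pupil_cost^2

  # per-wave marginal mean and count variance of the priced total
  mean_wave <- function(trend) sum(sr$mean_count * keep * sr$unit_cost) * trend
  var_wave <- function(trend) {
    m <- sr$mean_count * keep * trend
    pi0 <- 1 - (1 - sr$zero_prob) * keep   # effective zero probability
    mu <- m / (1 - pi0)
    v <- (1 - pi0) * mu * (1 + mu / sr$size) + pi0 * (1 - pi0) * mu^2
    sum(sr$unit_cost^2 * v)
  }
  M <- sum(w * vapply(config$cost_trend, mean_wave, numeric(1)))
  count_var <- sum(w^2 * vapply(config$cost_trend, var_wave, numeric(1)))
  within <- M^2 * (exp(sp2) - 1) + count_var

  icc <- config$icc_cost
  if (icc == 0) return(list(sigma = 0, mean_total = M, within_var = within))
  s2 <- log1p(icc / (1 - icc) * within / M^2)
  list(sigma = sqrt(s2), mean_total = M, within_var = within)
}

# Solve the intercept a so that the marginal prevalence over the school
# random effect u ~ N(0, sigma^2) and baseline drinking matches `target`.
solve_logit_intercept <- function(target, sigma, bh_prev, log_or_bh) {
  marginal <- function(a) {
    p_of <- function(bh) {
      if (sigma == 0) return(plogis(a + log_or_bh * bh))
      integrate(
        function(z) plogis(a + log_or_bh * bh + sigma * z) * dnorm(z),
        -Inf, Inf
      )$value
    }
    (1 - bh_prev) * p_of(0) + bh_prev * p_of(1) - target
  }
  lo <- qlogis(target) - 6
  hi <- qlogis(target) + 6
  if (marginal(lo) > 0 || marginal(hi) < 0) {
    abort("infeasible config: prevalence and ICC imply out-of-range school probabilities")
  }
  uniroot(marginal, c(lo, hi), tol = 1e-9)$root
}

#' Heavy-episodic-drinking threshold by sex
#'
#' Units of alcohol in a single episode at or above which the episode
#' counts as heavy: 6 for male pupils, 4.5 for female pupils.
#'
#' @param sex Character vector, `"male"` or `"female"`.
#' @return Numeric thresholds.
#' @export
hed_threshold <- function(sex) {
  ifelse(sex == "male", 6, 4.5)
}

# --- generation ---------------------------------------------------------------

#' Simulate a cluster-randomised trial
#'
#' Generates schools (with strata and random intercepts), pupils, per-wave
#' zero-inflated negative-binomial service-use counts whose implied
#' discounted cost embeds the configured true incremental cost, the binary
#' 33-month HED outcome with school-level variation around the arm
#' prevalences, and instrument-level missingness. Deterministic given
#' `seed`.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return An object of class `trial_simulation`: list with tibbles
#'   `schools`, `pupils`, `service_use` (long; only observed waves, `NA`
#'   counts for item-missing fields), `pupil_waves` (wave-missing flags)
#'   and a `truth` list (`delta_c`, `delta_e`, `icc_cost`, `icc_outcome`,
#'   `intervention_rate_factor`, `expected_total_cost`), plus the config
#'   and seed.
#' @examples
#' sim <- simulate_trial(trial_config(n_schools = 8, pupils_per_school = 20),
#'                       seed = 42)
#' sim$truth$delta_e
#' @export
simulate_trial <- function(config = trial_config(), seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  with_seed(seed, simulate_trial_impl(config, seed))
}

simulate_trial_impl <- function(config, seed) {
  n <- config$n_schools
  unit_costs <- unit_cost_table()

  sigma_out <- icc_to_sigma_outcome(config$icc_outcome)
  cost_cal <- icc_to_sigma_cost(config, unit_costs)
  sigma_cost <- cost_cal$sigma

  a_ctrl <- solve_logit_intercept(
    config$control_hed_prev, sigma_out,
    config$baseline_hed_prev, log(config$baseline_hed_or)
  )
  a_int <- solve_logit_intercept(
    config$intervention_hed_prev, sigma_out,
    config$baseline_hed_prev, log(config$baseline_hed_or)
  )

  # intervention scaling of post-baseline service rates: the discounted
  # total is linear in the window costs, so solve
  #   sum_{post waves} w_w * E_w * (f - 1) = true_delta_cost
  w <- window_total_weights(0.035)
  keep <- 1 - config$item_missing_prob
  base_wave_cost <- sum(
    config$service_rates$mean_count * keep *
      unit_costs$unit_cost[match(config$service_rates$service_id,
                                 unit_costs$service_id)]
  )
  post_expectation <- sum(w[2:4] * config$cost_trend[2:4]) * base_wave_cost
  f <- 1 + config$true_delta_cost / post_expectation
  if (f <= 0) {
    abort("infeasible config: true_delta_cost implies non-positive service rates")
  }

  # schools ------------------------------------------------------------------
  fsm_ranges <- list(low = c(0, 15.4), moderate = c(15.5, 30.4), high = c(30.5, 60))
  band <- sample(names(config$fsm_probs), n, TRUE, prob = config$fsm_probs)
  schools <- tibble(
    school_id = sprintf("S%03d", seq_len(n)),
    arm = sample(rep(arm_levels(), length.out = n)),
    location = ifelse(runif(n) < config$location_split, "NI", "Scotland"),
    fsm_pct = vapply(band, function(b) {
      r <- fsm_ranges[[b]]
      round(runif(1, r[1], r[2]), 1)
    }, numeric(1)),
    school_type = sample(names(config$school_type_probs), n, TRUE,
                         prob = config$school_type_probs),
    n_pupils = pmax(
      10L,
      rnbinom(n, mu = config$pupils_per_school, size = config$pupil_dispersion)
    ),
    u_cost = rnorm(n, -sigma_cost^2 / 2, sigma_cost),
    u_outcome = rnorm(n, 0, sigma_out)
  ) |>
    mutate(fsm_band = as.character(fsm_band(.data$fsm_pct)))

  # pupils -------------------------------------------------------------------
  np <- sum(schools$n_pupils)
  pupils <- tibble(
    pupil_id = sprintf("P%05d", seq_len(np)),
    school_id = rep(schools$school_id, schools$n_pupils)
  ) |>
    left_join(
      select(schools, "school_id", "arm", "location", "fsm_band",
             "school_type", "u_cost", "u_outcome"),
      by = "school_id"
    ) |>
    mutate(
      sex = sample(c("male", "female"), np, TRUE),
      baseline_hed = rbinom(np, 1, config$baseline_hed_prev),
      v_cost = rnorm(np, -config$sigma_pupil_cost^2 / 2,
                     config$sigma_pupil_cost)
    )

  a_arm <- ifelse(pupils$arm == "intervention", a_int, a_ctrl)
  p33 <- plogis(
    a_arm + log(config$baseline_hed_or) * pupils$baseline_hed +
      pupils$u_outcome
  )
  if (config$outcome_mode == "units") {
    # worst-episode units with P(units >= threshold) = p33 per pupil
    sdlog <- 0.9
    thr <- hed_threshold(pupils$sex)
    units <- round(exp(log(thr) - sdlog * qnorm(1 - p33) + sdlog * rnorm(np)), 1)
    pupils$episode_units <- units
    pupils$hed33 <- as.integer(units >= thr)
  } else {
    pupils$hed33 <- rbinom(np, 1, p33)
  }
  p12 <- plogis(
    qlogis(config$hed12_prev) + 1.0 * pupils$hed33 +
      1.2 * pupils$baseline_hed + pupils$u_outcome
  )
  pupils$hed12 <- rbinom(np, 1, p12)

  # missingness ---------------------------------------------------------------
  miss <- config$missingness
  lin_extra <- function(base_prob) {
    lp <- qlogis(base_prob)
    if (miss$mechanism %in% c("MAR", "MNAR")) {
      lp <- lp + log(miss$or_fsm_high) * (pupils$fsm_band == "high") +
        log(miss$or_baseline_hed) * pupils$baseline_hed
    }
    if (miss$mechanism == "MNAR" && config$sigma_pupil_cost > 0) {
      z <- (pupils$v_cost + config$sigma_pupil_cost^2 / 2) /
        config$sigma_pupil_cost
      lp <- lp + log(miss$or_mnar_per_sd) * z
    }
    lp
  }
  lp_wave <- lin_extra(miss$wave_missing_base_prob)
  wave_missing <- matrix(
    rbinom(np * 4, 1, plogis(rep(lp_wave, 4))) == 1,
    nrow = np, ncol = 4, dimnames = list(NULL, wave_levels())
  )
  hed33_missing <- rbinom(np, 1, plogis(lin_extra(miss$outcome_missing_base_prob))) == 1
  pupils$hed33[hed33_missing] <- NA_integer_
  # the interim drinking item travels on the 12-month instrument
  pupils$hed12[wave_missing[, "m7_12"]] <- NA_integer_

  pupil_waves <- tibble(
    pupil_id = rep(pupils$pupil_id, each = 4),
    wave = rep(wave_levels(), np),
    wave_missing = as.vector(t(wave_missing))
  )

  # service counts for observed waves ----------------------------------------
  sr <- config$service_rates
  ns <- nrow(sr)
  obs <- !wave_missing
  long <- tidyr::expand_grid(
    i = seq_len(np),
    wave_idx = 1:4,
    s = seq_len(ns)
  ) |>
    filter(obs[cbind(.data$i, .data$wave_idx)])

  trend <- config$cost_trend[long$wave_idx]
  int_factor <- ifelse(
    pupils$arm[long$i] == "intervention" & long$wave_idx > 1, f, 1
  )
  mu_use <- sr$mean_count[long$s] / (1 - sr$zero_prob[long$s]) *
    trend * int_factor * exp(pupils$u_cost[long$i] + pupils$v_cost[long$i])
  uses <- rbinom(nrow(long), 1, 1 - sr$zero_prob[long$s])
  counts <- integer(nrow(long))
  pos <- uses == 1
  counts[pos] <- rnbinom(sum(pos), mu = mu_use[pos], size = sr$size[long$s[pos]])
  counts[runif(nrow(long)) < config$item_missing_prob] <- NA_integer_

  service_use <- tibble(
    pupil_id = pupils$pupil_id[long$i],
    wave = wave_levels()[long$wave_idx],
    service_id = sr$service_id[long$s],
    count = counts
  )

  truth <- list(
    delta_c = config$true_delta_cost,
    delta_e = config$control_hed_prev - config$intervention_hed_prev,
    icc_cost = config$icc_cost,
    icc_outcome = config$icc_outcome,
    intervention_rate_factor = f,
    expected_total_cost = cost_cal$mean_total,
    sigma_cost = sigma_cost,
    sigma_outcome = sigma_out
  )

  structure(
    list(
      schools = select(schools, -"u_cost", -"u_outcome"),
      pupils = select(pupils, -"u_cost", -"u_outcome", -"v_cost"),
      service_use = service_use,
      pupil_waves = pupil_waves,
      truth = truth,
      config = config,
      seed = seed
    ),
    class = "trial_simulation"
  )
}

#' @export
print.trial_simulation <- function(x, ...) {
  cat(sprintf(
    "<trial_simulation> %d schools, %d pupils (seed %s)\n",
    nrow(x$schools), nrow(x$pupils), format(x$seed)
  ))
  cat(sprintf(
    "  truth: delta_c = %.1f, delta_e = %.3f\n",
    x$truth$delta_c, x$truth$delta_e
  ))
  invisible(x)
}

#' Assemble the analysis dataset from a simulated (or real-shaped) trial
#'
#' Runs the costing chain on the service-use records and joins pupil and
#' school information into the pupil-level analysis table. The programme
#' cost is *not* added here; see [add_programme_cost()].
#'
#' @param sim A `trial_simulation`, or a list with elements `pupils`,
#'   `schools`, `service_use` and optionally `pupil_waves`.
#' @param unit_costs Unit-cost table.
#' @param discount_rate Annual discount rate for the cost totals.
#' @return A tibble with one row per pupil: ids, arm, strata,
#'   `baseline_cost`, `baseline_hed`, `hed12`, `total_cost` (discounted
#'   public-sector cost, `NA` if cost-incomplete), sector costs, `hed33`
#'   and `complete` (cost-complete *and* outcome observed).
#' @export
analysis_dataset <- function(sim,
                             unit_costs = unit_cost_table(),
                             discount_rate = 0.035) {
  costs <- build_cost_dataset(
    sim$service_use,
    unit_costs = unit_costs,
    discount_rate = discount_rate,
    pupil_waves = sim$pupil_waves
  )
  sim$pupils |>
    select(any_of(c(
      "pupil_id", "school_id", "arm", "location", "fsm_band", "school_type",
      "sex", "baseline_hed", "hed12", "hed33"
    ))) |>
    left_join(costs, by = "pupil_id") |>
    rename(total_cost = "total_discounted") |>
    mutate(complete = .data$complete & !is.na(.data$hed33))
}

#' Descriptive summary of a trial dataset
#'
#' Per-arm pupil counts, completeness fractions, mean costs by sector
#' (among cost-complete pupils) and outcome prevalences (among observed
#' outcomes) -- the eyeballing table for generated data.
#'
#' @param data An analysis dataset (see [analysis_dataset()]) or a
#'   `trial_simulation` (assembled automatically).
#' @return A tibble with one row per arm.
#' @export
describe_trial <- function(data) {
  if (inherits(data, "trial_simulation")) data <- analysis_dataset(data)
  data <- as_tibble(data)
  if (nrow(data) == 0) {
    return(tibble(
      arm = character(), n = integer(), complete_fraction = double(),
      mean_total_cost = double(), mean_education_cost = double(),
      mean_health_cost = double(), mean_criminal_cost = double(),
      baseline_hed_prev = double(), hed33_prev = double()
    ))
  }
  data |>
    group_by(.data$arm) |>
    summarise(
      n = dplyr::n(),
      complete_fraction = mean(.data$complete),
      mean_total_cost = mean(.data$total_cost, na.rm = TRUE),
      mean_education_cost = mean(.data$education_cost, na.rm = TRUE),
      mean_health_cost = mean(.data$health_cost, na.rm = TRUE),
      mean_criminal_cost = mean(.data$criminal_cost, na.rm = TRUE),
      baseline_hed_prev = mean(.data$baseline_hed),
      hed33_prev = mean(.data$hed33, na.rm = TRUE),
      .groups = "drop"
    )
}
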