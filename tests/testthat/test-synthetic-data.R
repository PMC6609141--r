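test_that("simulation is reproducible by seed and seeds differentiate", {
  cfg <- trial_config(n_schools = 8, pupils_per_school = 15)
  a <- simulate_trial(cfg, seed = 5)
  b <- simulate_trial(cfg, seed = 5)
  expect_identical(a$service_use, b$service_use)
  expect_identical(a$pupils, b$pupils)
  c2 <- simulate_trial(cfg, seed = 6)
  expect_false(identical(a$service_use, c2$service_use))
})

test_that("configuration errors are caught up front", {
  expect_error(trial_config(control_hed_prev = 1.2), "infeasible")
  expect_error(trial_config(fsm_probs = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(trial_config(icc_cost = 1), "ICC")
  expect_error(trial_config(n_schools = 2), "at least 4")
  # an arm-cost reduction larger than post-baseline spending is impossible
  expect_error(
    simulate_trial(trial_config(n_schools = 8, true_delta_cost = -1e6), seed = 1),
    "non-positive service rates"
  )
})

test_that("zero missingness makes every pupil complete", {
  sim <- simulate_trial(
    trial_config(n_schools = 10, pupils_per_school = 20,
                 item_missing_prob = 0,
                 missingness = missingness_config(
                   mechanism = "MCAR",
                   wave_missing_base_prob = 0,
                   outcome_missing_base_prob = 0
                 )),
    seed = 12
  )
  dat <- analysis_dataset(sim)
  expect_true(all(dat$complete))
  expect_true(all(!is.na(dat$total_cost)))
  expect_equal(describe_trial(dat)$complete_fraction, c(1, 1))
})

test_that("default missingness leaves roughly two-thirds of pupils complete", {
  sim <- simulate_trial(
    trial_config(n_schools = 60, pupils_per_school = 60), seed = 81
  )
  d <- describe_trial(sim)
  expect_true(all(d$complete_fraction > 0.60 & d$complete_fraction < 0.72))
})

test_that("schools are balanced 1:1 and carry consistent strata", {
  sim <- simulate_trial(trial_config(n_schools = 30, pupils_per_school = 10),
                        seed = 2)
  expect_equal(sum(sim$schools$arm == "intervention"), 15)
  expect_equal(sum(sim$schools$arm == "control"), 15)
  expect_equal(sim$schools$fsm_band,
               as.character(fsm_band(sim$schools$fsm_pct)))
  # each school maps to exactly one stratum combination in the pupil table
  per_school <- sim$pupils |>
    dplyr::distinct(school_id, arm, location, fsm_band, school_type) |>
    dplyr::count(school_id)
  expect_true(all(per_school$n == 1))
})

test_that("the truth object reflects the configured margins", {
  cfg <- trial_config()
  sim <- simulate_trial(trial_config(n_schools = 8, pupils_per_school = 10),
                        seed = 3)
  expect_equal(sim$truth$delta_e, cfg$control_hed_prev - cfg$intervention_hed_prev)
  expect_equal(sim$truth$delta_c, cfg$true_delta_cost)
  expect_lt(sim$truth$intervention_rate_factor, 1) # cost-saving configuration
})

test_that("arm prevalences and the cost offset are recovered at scale", {
  sim <- simulate_trial(
    trial_config(n_schools = 80, pupils_per_school = 120,
                 item_missing_prob = 0,
                 missingness = missingness_config(
                   mechanism = "MCAR",
                   wave_missing_base_prob = 0, outcome_missing_base_prob = 0
                 )),
    seed = 55
  )
  prev <- sim$pupils |>
    dplyr::group_by(arm) |>
    dplyr::summarise(p = mean(hed33), .groups = "drop")
  expect_lt(abs(prev$p[prev$arm == "control"] - 0.23), 0.02)
  expect_lt(abs(prev$p[prev$arm == "intervention"] - 0.15), 0.02)

  dat <- analysis_dataset(sim)
  arm_means <- dat |>
    dplyr::group_by(arm) |>
    dplyr::summarise(m = mean(total_cost), .groups = "drop")
  raw_diff <- arm_means$m[arm_means$arm == "intervention"] -
    arm_means$m[arm_means$arm == "control"]
  # the embedded offset is -30; between-school noise leaves a wide band
  # (school-level SE of the raw arm difference is roughly 65 here)
  expect_lt(abs(raw_diff - sim$truth$delta_c), 200)
})

test_that("empirical school-level cost ICC is near the configured target", {
  sim <- simulate_trial(
    trial_config(n_schools = 120, pupils_per_school = 80,
                 item_missing_prob = 0,
                 missingness = missingness_config(
                   mechanism = "MCAR",
                   wave_missing_base_prob = 0, outcome_missing_base_prob = 0
                 )),
    seed = 17
  )
  dat <- analysis_dataset(sim) |> dplyr::filter(arm == "control")
  # one-way ANOVA moment estimator of the intraclass correlation
  grp <- split(dat$total_cost, dat$school_id)
  k <- length(grp)
  n_i <- lengths(grp)
  N <- sum(n_i)
  gm <- mean(dat$total_cost)
  msb <- sum(n_i * (vapply(grp, mean, numeric(1)) - gm)^2) / (k - 1)
  msw <- sum(vapply(grp, function(x) sum((x - mean(x))^2), numeric(1))) / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  icc_hat <- (msb - msw) / (msb + (n0 - 1) * msw)
  expect_equal(icc_hat, sim$truth$icc_cost, tolerance = 0.02)
})

test_that("units outcome mode applies the sex-specific thresholds", {
  sim <- simulate_trial(
    trial_config(n_schools = 20, pupils_per_school = 50,
                 outcome_mode = "units"),
    seed = 23
  )
  p <- sim$pupils
  expect_true(all(c("episode_units", "sex") %in% names(p)))
  derived <- as.integer(p$episode_units >= hed_threshold(p$sex))
  observed <- !is.na(p$hed33)
  expect_equal(p$hed33[observed], derived[observed])
  # prevalence still near the configured margins
  prev <- mean(p$hed33[p$arm == "control"], na.rm = TRUE)
  expect_lt(abs(prev - 0.23), 0.03)
})

test_that("MNAR missingness selects lighter service users into the complete cases", {
  sim <- simulate_trial(
    trial_config(n_schools = 40, pupils_per_school = 60), seed = 61
  )
  dat <- analysis_dataset(sim)
  # complete pupils report lower pre-baseline costs than the incomplete
  # (baseline cost is observed whenever the pre-baseline wave is)
  base <- dat |>
    dplyr::filter(!is.na(baseline_cost)) |>
    dplyr::group_by(complete) |>
    dplyr::summarise(m = mean(baseline_cost), .groups = "drop")
  expect_lt(base$m[base$complete], base$m[!base$complete])
})

test_that("describe_trial handles empty and complete datasets", {
  empty <- analysis_dataset(small_sim())[0, ]
  d0 <- describe_trial(empty)
  expect_equal(nrow(d0), 0)

  sim <- simulate_trial(
    trial_config(n_schools = 6, pupils_per_school = 8,
                 item_missing_prob = 0,
                 missingness = missingness_config(
                   mechanism = "MCAR",
                   wave_missing_base_prob = 0, outcome_missing_base_prob = 0
                 )),
    seed = 9
  )
  d <- describe_trial(sim)
  expect_equal(d$complete_fraction, c(1, 1))
  expect_equal(sum(d$n), nrow(sim$pupils))
})
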