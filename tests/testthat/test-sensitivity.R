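test_that("Rubin pooling matches the closed forms", {
  p0 <- pool_rubin(c(2, 2, 2), c(1, 1, 1))
  expect_equal(p0$estimate, 2)
  expect_equal(p0$variance, 1) # zero between-imputation variance

  p1 <- pool_rubin(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p1$estimate, 2)
  expect_equal(p1$variance, 1 + (1 + 1 / 3) * 1)

  # order invariance
  p2 <- pool_rubin(c(3, 1, 2), c(1, 1, 1))
  expect_equal(p2$estimate, p1$estimate)
  expect_equal(p2$variance, p1$variance)

  expect_error(pool_rubin(c(1, 2), c(1, 1, 1)), "same length")
  expect_error(pool_rubin(1, 1), "at least 2")
})

test_that("imputation is a no-op on complete data and deterministic by seed", {
  dat <- analysis_dataset(small_sim()) |>
    dplyr::filter(complete) |>
    dplyr::select(-dplyr::any_of("hed12"))
  done <- impute_mice(dat, m = 3, seed = 1)
  expect_length(done, 3)
  for (d in done) expect_equal(d, dat)

  # with missingness: same seed, same completions; different seed differs
  full <- analysis_dataset(small_sim())
  a <- impute_mice(full, m = 2, seed = 7, cycles = 3)
  b <- impute_mice(full, m = 2, seed = 7, cycles = 3)
  expect_equal(a[[1]]$total_cost, b[[1]]$total_cost)
  c2 <- impute_mice(full, m = 2, seed = 8, cycles = 3)
  expect_false(identical(a[[1]]$total_cost, c2[[1]]$total_cost))
})

test_that("PMM only imputes observed donor values", {
  withr::local_seed(4)
  n <- 120
  dat <- tibble::tibble(
    pupil_id = as.character(seq_len(n)),
    school_id = rep(sprintf("S%d", 1:6), each = n / 6),
    arm = rep(c("control", "intervention"), each = n / 2),
    location = "NI", fsm_band = "low", school_type = "coed",
    baseline_cost = round(runif(n, 0, 100), 2),
    baseline_hed = rbinom(n, 1, 0.1),
    total_cost = round(500 + 3 * runif(n, 0, 100) + rnorm(n, 0, 40), 2),
    hed33 = rbinom(n, 1, 0.2)
  )
  dat$total_cost[sample(n, 30)] <- NA
  observed <- dat$total_cost[!is.na(dat$total_cost)]
  done <- impute_mice(dat, m = 2, seed = 2, cycles = 5)
  for (d in done) {
    imputed <- d$total_cost[is.na(dat$total_cost)]
    expect_true(all(imputed %in% observed))
  }
})

test_that("a variable with no observed values cannot be imputed", {
  dat <- analysis_dataset(small_sim())
  dat$total_cost <- NA_real_
  expect_error(impute_mice(dat, m = 2, seed = 1), "no observed values")
})

test_that("MCAR missingness leaves the pooled effect near the complete-case effect", {
  sim <- simulate_trial(
    trial_config(n_schools = 24, pupils_per_school = 40,
                 missingness = missingness_config(mechanism = "MCAR",
                                                  wave_missing_base_prob = 0.05,
                                                  outcome_missing_base_prob = 0.08)),
    seed = 31
  )
  dat <- analysis_dataset(sim) |> add_programme_cost(15)
  cc <- fit_effect_model(dplyr::filter(dat, complete))$delta

  done <- impute_mice(dat, m = 5, seed = 2, cycles = 5)
  pooled <- pool_rubin(
    vapply(done, function(d) fit_effect_model(d)$delta, numeric(1)),
    vapply(done, function(d) fit_effect_model(d)$se^2, numeric(1))
  )
  # both estimate the same effect; allow Monte-Carlo noise on 960 pupils
  expect_lt(abs(pooled$estimate - cc), 0.05)
})

test_that("cost perturbation variants scale the cost difference exactly", {
  sim <- small_sim()
  primary <- run_variant(sim, "complete_case_primary", B = 40, seed = 6)
  up <- run_variant(sim, "costs_up_5", B = 40, seed = 6)
  down <- run_variant(sim, "costs_down_5", B = 40, seed = 6)
  expect_equal(up$delta_c, primary$delta_c * 1.05, tolerance = 1e-8)
  expect_equal(down$delta_c, primary$delta_c * 0.95, tolerance = 1e-8)
  expect_equal(up$ci_c_lo, primary$ci_c_lo * 1.05, tolerance = 1e-8)
  # effects and their intervals are untouched
  expect_equal(up$delta_e, primary$delta_e)
  expect_equal(c(up$ci_e_lo, up$ci_e_hi),
               c(primary$ci_e_lo, primary$ci_e_hi))
  expect_equal(down$delta_e, primary$delta_e)
})

test_that("the 1.5% discount variant matches an independent recomputation", {
  sim <- small_sim()
  v <- run_variant(sim, "discount_1_5", B = 30, seed = 4)

  # independent path: recost at 1.5%, same models, outcome discounted
  dat <- analysis_dataset(sim, discount_rate = 0.015) |>
    add_programme_cost(round(programme_cost()$per_pupil))
  cc <- dplyr::filter(dat, complete)
  est <- cluster_bootstrap(cc, B = 30, seed = 4)
  expect_equal(v$delta_c, est$delta_c, tolerance = 1e-9)
  expect_equal(v$delta_e, est$delta_e * (1.015)^-2, tolerance = 1e-12)

  # and per-pupil totals agree with the brute-force oracle at 1.5%
  uc <- unit_cost_table()
  sub <- dat[!is.na(dat$total_cost), ][1:3, ]
  for (p in sub$pupil_id) {
    oracle <- oracle_pupil_total(sim$service_use, p, uc, rate = 0.015)
    expect_equal(sub$total_cost[sub$pupil_id == p] - 15 *
                   (sub$arm[sub$pupil_id == p] == "intervention"),
                 oracle$total, tolerance = 1e-9)
  }
})

test_that("cluster-only variant drops baseline adjustment but keeps clustering", {
  sim <- small_sim()
  v <- run_variant(sim, "cluster_only", B = 20, seed = 9)
  dat <- analysis_dataset(sim) |>
    add_programme_cost(round(programme_cost()$per_pupil))
  cc <- dplyr::filter(dat, complete)
  expect_equal(v$delta_c, fit_cost_model(cc, adjusted = FALSE)$delta,
               tolerance = 1e-9)
  expect_error(run_variant(sim, "no_such_variant"), "unknown variant")
})

test_that("variant runs are reproducible for a fixed seed", {
  sim <- small_sim()
  a <- run_variant(sim, "complete_case_primary", B = 15, seed = 3)
  b <- run_variant(sim, "complete_case_primary", B = 15, seed = 3)
  expect_equal(a$delta_c, b$delta_c)
  expect_equal(a$ceac[[1]], b$ceac[[1]])
})
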