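test_that("default unit-cost ledger matches the published table", {
  tbl <- unit_cost_table()
  expect_equal(nrow(tbl), 17)
  expect_equal(
    as.list(table(tbl$sector)),
    list(criminal_justice = 2L, education = 5L, health = 10L)
  )
  expect_equal(tbl$unit_cost[tbl$service_id == "gp_surgery"], 46.00)
  expect_equal(tbl$unit_cost[tbl$service_id == "accident_emergency"], 233.00)
  expect_equal(tbl$unit_cost[tbl$service_id == "overnight_stay"], 658.33)
  expect_false(anyDuplicated(tbl$service_id) > 0)
  expect_true(all(tbl$unit_cost > 0))
})

test_that("wave costing prices counts, zeroes item-missing fields, splits sectors", {
  # one GP visit + one A&E attendance
  use <- tibble::tibble(
    pupil_id = "p1", wave = "m7_12",
    service_id = c("gp_surgery", "accident_emergency"), count = c(1L, 1L)
  )
  out <- cost_waves(use)
  expect_equal(out$cost, 279.00)
  expect_equal(out$health_cost, 279.00)
  expect_equal(out$education_cost, 0)

  # all-zero counts
  zero <- tibble::tibble(
    pupil_id = "p2", wave = "m19_24",
    service_id = unit_cost_table()$service_id,
    count = 0L
  )
  outz <- cost_waves(zero)
  expect_equal(outz$cost, 0)
  expect_equal(outz$education_cost + outz$health_cost + outz$criminal_cost, 0)

  # item-missing police field is costed as zero use
  mixed <- tibble::tibble(
    pupil_id = "p3", wave = "m28_33",
    service_id = c("overnight_stay", "police"), count = c(1L, NA)
  )
  outm <- cost_waves(mixed)
  expect_equal(outm$cost, 658.33)
  expect_equal(outm$criminal_cost, 0)
})

test_that("wave costing rejects unknown services and negative counts", {
  bad_id <- tibble::tibble(pupil_id = "p", wave = "m7_12",
                           service_id = "spa_day", count = 1L)
  expect_error(cost_waves(bad_id), "spa_day")
  bad_count <- tibble::tibble(pupil_id = "p", wave = "m7_12",
                              service_id = "gp_surgery", count = -1L)
  expect_error(cost_waves(bad_count), "negative")
})

test_that("sector subtotals always sum exactly to the wave total", {
  use <- make_toy_cohort(
    n_pupils = 8,
    services = c("gp_surgery", "school_nurse", "police", "overnight_stay"),
    seed = 7
  )
  out <- cost_waves(use)
  expect_equal(out$education_cost + out$health_cost + out$criminal_cost,
               out$cost, tolerance = 1e-12)
})

test_that("trajectory interpolation reproduces flat, zero and oracle cases", {
  flat <- interpolate_trajectory(c(60, 60, 60, 60))
  expect_equal(flat, rep(10, 33))
  expect_equal(sum(flat), 330)

  expect_equal(interpolate_trajectory(c(0, 0, 0, 0)), rep(0, 33))

  # rising trend checked month-by-month against the brute-force oracle
  windows <- c(pre_baseline = 0, m7_12 = 60, m19_24 = 120, m28_33 = 180)
  expect_equal(interpolate_trajectory(windows), oracle_monthly_costs(windows),
               tolerance = 1e-12)

  # a batch of random window profiles
  withr::local_seed(5)
  for (i in 1:20) {
    w <- runif(4, 0, 500)
    expect_equal(interpolate_trajectory(w), oracle_monthly_costs(w),
                 tolerance = 1e-10)
  }
})

test_that("interpolation refuses incomplete window sets", {
  expect_error(interpolate_trajectory(c(pre_baseline = 1, m7_12 = 2, m19_24 = 3)),
               "incomplete")
  expect_error(interpolate_trajectory(c(1, 2, NA, 4)), "incomplete")
})

test_that("discounting follows study-year boundaries", {
  m <- rep(1, 33)
  expect_equal(discount_total(m, 0), 33)

  m18 <- numeric(33); m18[18] <- 100
  expect_equal(discount_total(m18, 0.035), 100 / 1.035)
  m30 <- numeric(33); m30[30] <- 100
  expect_equal(discount_total(m30, 0.035), 100 / 1.035^2)
  m12 <- numeric(33); m12[12] <- 100
  expect_equal(discount_total(m12, 0.035), 100) # year 1 undiscounted

  expect_error(discount_total(m, -0.01), "non-negative")
})

test_that("discounted total is non-increasing in the rate", {
  withr::local_seed(11)
  m <- runif(33, 0, 50)
  rates <- seq(0, 0.10, by = 0.005)
  totals <- vapply(rates, function(r) discount_total(m, r), numeric(1))
  expect_true(all(diff(totals) <= 1e-12))
})

test_that("cost dataset applies the complete-case rule and matches the oracle", {
  missing <- list(T02 = "m19_24", T04 = c("pre_baseline", "m28_33"))
  use <- make_toy_cohort(n_pupils = 5, missing_waves = missing, seed = 3)
  out <- build_cost_dataset(use)
  uc <- unit_cost_table()

  expect_equal(nrow(out), 5)
  expect_equal(out$complete,
               !out$pupil_id %in% c("T02", "T04"))
  # incomplete pupils: totals absent, baseline kept when pre wave observed
  expect_true(is.na(out$total_discounted[out$pupil_id == "T02"]))
  expect_false(is.na(out$baseline_cost[out$pupil_id == "T02"]))
  expect_true(is.na(out$baseline_cost[out$pupil_id == "T04"]))

  for (p in out$pupil_id) {
    oracle <- oracle_pupil_total(use, p, uc)
    expect_equal(out$total_discounted[out$pupil_id == p], oracle$total,
                 tolerance = 1e-9, label = p)
    expect_equal(out$baseline_cost[out$pupil_id == p], oracle$windows[1],
                 label = p)
  }
})

test_that("cost dataset rejects duplicated service rows", {
  use <- tibble::tibble(
    pupil_id = "p1", wave = "m7_12",
    service_id = c("gp_surgery", "gp_surgery"), count = c(1L, 2L)
  )
  expect_error(build_cost_dataset(use), "duplicate")
})

test_that("explicit wave-missing flags are honoured and contradictions rejected", {
  use <- tibble::tibble(
    pupil_id = "p1",
    wave = c("pre_baseline", "m7_12", "m19_24", "m28_33"),
    service_id = "gp_surgery", count = 1L
  )
  pw <- tidyr::expand_grid(pupil_id = c("p1", "p2"),
                           wave = c("pre_baseline", "m7_12", "m19_24", "m28_33")) |>
    dplyr::mutate(wave_missing = pupil_id == "p2")
  out <- build_cost_dataset(use, pupil_waves = pw)
  expect_equal(nrow(out), 2) # p2 appears, fully missing
  expect_false(out$complete[out$pupil_id == "p2"])

  pw_bad <- dplyr::mutate(pw, wave_missing = TRUE)
  expect_error(build_cost_dataset(use, pupil_waves = pw_bad), "flagged missing")
})

test_that("pupil totals scale exactly with the unit costs and decompose by sector", {
  use <- make_toy_cohort(n_pupils = 6, seed = 13)
  uc <- unit_cost_table()
  out1 <- build_cost_dataset(use, unit_costs = uc)
  uc_k <- dplyr::mutate(uc, unit_cost = unit_cost * 3.7)
  out_k <- build_cost_dataset(use, unit_costs = uc_k)
  expect_equal(out_k$total_discounted, out1$total_discounted * 3.7,
               tolerance = 1e-12)

  sums <- out1$education_cost + out1$health_cost + out1$criminal_cost
  expect_equal(sums[out1$complete], out1$total_discounted[out1$complete],
               tolerance = 1e-9)
})

test_that("full costing chain matches the brute-force oracle on random cohorts", {
  for (seed in c(21, 22, 23)) {
    use <- make_toy_cohort(
      n_pupils = 10,
      services = c("gp_surgery", "school_nurse", "police"),
      missing_waves = list(T03 = "m7_12"),
      seed = seed
    )
    out <- build_cost_dataset(use)
    uc <- unit_cost_table()
    for (p in unique(use$pupil_id)) {
      expect_equal(
        out$total_discounted[out$pupil_id == p],
        oracle_pupil_total(use, p, uc)$total,
        tolerance = 1e-9, label = sprintf("seed %d pupil %s", seed, p)
      )
    }
  }
})
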