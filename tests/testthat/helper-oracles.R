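# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorised implementations.

# Piecewise-linear interpolation oracle: monthly rate at month centre
# m - 0.5, anchors at window midpoints, constant extrapolation at the
# right edge. Explicit segment search, no approx().
oracle_monthly_costs <- function(windows) {
  anchors <- c(-3, 9.5, 21.5, 30.5)
  rates <- windows / 6
  out <- numeric(33)
  for (m in 1:33) {
    t <- m - 0.5
    if (t <= anchors[1]) {
      out[m] <- rates[1]
    } else if (t >= anchors[4]) {
      out[m] <- rates[4]
    } else {
      for (j in 1:3) {
        if (t >= anchors[j] && t <= anchors[j + 1]) {
          frac <- (t - anchors[j]) / (anchors[j + 1] - anchors[j])
          out[m] <- rates[j] + frac * (rates[j + 1] - rates[j])
          break
        }
      }
    }
  }
  out
}

oracle_discount <- function(monthly, rate) {
  total <- 0
  for (m in 1:33) {
    div <- if (m <= 12) 1 else if (m <= 24) (1 + rate) else (1 + rate)^2
    total <- total + monthly[m] / div
  }
  total
}

# Spreadsheet-style costing of one pupil from long-format counts:
# price each wave by explicit summation (NA counts as zero use), then
# interpolate + discount via the oracles above. Returns NA total if any
# wave is absent.
oracle_pupil_total <- function(service_use, pupil, unit_costs, rate = 0.035) {
  waves <- c("pre_baseline", "m7_12", "m19_24", "m28_33")
  wcost <- rep(NA_real_, 4)
  for (w in seq_along(waves)) {
    rows <- service_use[service_use$pupil_id == pupil &
                          service_use$wave == waves[w], ]
    if (nrow(rows) == 0) next
    total <- 0
    for (r in seq_len(nrow(rows))) {
      cnt <- rows$count[r]
      if (is.na(cnt)) cnt <- 0
      uc <- unit_costs$unit_cost[unit_costs$service_id == rows$service_id[r]]
      total <- total + cnt * uc
    }
    wcost[w] <- total
  }
  if (any(is.na(wcost))) {
    return(list(windows = wcost, total = NA_real_))
  }
  list(windows = wcost,
       total = oracle_discount(oracle_monthly_costs(wcost), rate))
}

# Random small service-use cohort over a subset of services.
make_toy_cohort <- function(n_pupils = 5, services = c("gp_surgery", "school_nurse", "police"),
                            missing_waves = list(), seed = 1) {
  withr::local_seed(seed)
  waves <- c("pre_baseline", "m7_12", "m19_24", "m28_33")
  rows <- list()
  for (p in seq_len(n_pupils)) {
    pid <- sprintf("T%02d", p)
    for (w in waves) {
      if (w %in% (missing_waves[[pid]] %||% character())) next
      for (s in services) {
        cnt <- sample(0:3, 1)
        if (runif(1) < 0.1) cnt <- NA_integer_
        rows[[length(rows) + 1]] <- tibble::tibble(
          pupil_id = pid, wave = w, service_id = s, count = cnt
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal balanced analysis dataset: n_schools per arm, each with
# `pupils` identical-covariate pupils; outcomes supplied by caller
# functions of (arm, school index, pupil index).
make_analysis_data <- function(n_schools_per_arm = 3, pupils = 4,
                               cost_fn = function(arm, s, p) 100,
                               hed_fn = function(arm, s, p) 0L) {
  rows <- list()
  for (arm in c("control", "intervention")) {
    for (s in seq_len(n_schools_per_arm)) {
      sid <- sprintf("%s_%d", substr(arm, 1, 3), s)
      for (p in seq_len(pupils)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          pupil_id = sprintf("%s_p%d", sid, p),
          school_id = sid, arm = arm,
          location = c("NI", "Scotland")[1 + s %% 2],
          fsm_band = c("low", "moderate", "high")[1 + (s + p) %% 3],
          school_type = "coed",
          baseline_cost = 10 * p, baseline_hed = p %% 2,
          total_cost = cost_fn(arm, s, p),
          hed33 = hed_fn(arm, s, p),
          complete = TRUE
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Small simulated trial shared by slower tests (built once per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_trial(
        trial_config(n_schools = 20, pupils_per_school = 30), seed = 2024
      )
    }
    cache
  }
})
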