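# Costing: price per-wave service-use counts, interpolate monthly cost rates
# over the survey gaps, discount, and assemble per-pupil 33-month totals.
#
# The chain is linear in the four window costs, so the interpolation is
# implemented once as a 33 x 4 weight matrix (monthly rate at each month
# centre as a linear functional of the window costs) and reused everywhere,
# including the sector decomposition, which therefore sums to the pupil
# total exactly.

# Weight matrix mapping the four window costs to the 33 monthly costs.
# Window cost -> monthly rate (cost / 6) anchored at the window midpoint;
# the rate at month centre m - 0.5 is linearly interpolated between the
# bracketing anchors, with constant extrapolation beyond the last anchor.
interp_weight_matrix <- function() {
  mids <- wave_midpoints()
  centres <- (1:33) - 0.5
  W <- vapply(seq_along(mids), function(j) {
    basis <- numeric(length(mids))
    basis[j] <- 1 / 6
    approx(mids, basis, xout = centres, rule = 2)$y
  }, numeric(33))
  dimnames(W) <- list(NULL, wave_levels())
  W
}

#' Interpolate a pupil's cost trajectory over the survey gaps
#'
#' Converts four observed six-month window costs into 33 monthly costs.
#' Each window is converted to a monthly rate (window cost / 6) anchored at
#' the window midpoint (months -3, 9.5, 21.5 and 30.5); the rate for month
#' m is the linear interpolation of the anchors evaluated at the month
#' centre m - 0.5, with constant extrapolation of the last rate beyond
#' month 30.5. The pre-baseline window anchors the left end of the trend
#' but its own months (before month 1) never enter the output.
#'
#' @param window_costs Numeric vector of the four window costs in pounds,
#'   named by wave (`pre_baseline`, `m7_12`, `m19_24`, `m28_33`) or unnamed
#'   in that order. All four must be present and non-missing.
#' @return Numeric vector of length 33: the cost attributed to each of
#'   months 1--33.
#' @examples
#' # A flat trend: every window 60 -> every month 10, total 330
#' sum(interpolate_trajectory(c(60, 60, 60, 60)))
#' @export
interpolate_trajectory <- function(window_costs) {
  wl <- wave_levels()
  if (!is.null(names(window_costs))) {
    missing <- setdiff(wl, names(window_costs))
    if (length(missing) > 0) {
      abort(sprintf(
        "incomplete trajectory: window(s) absent: %s",
        paste(missing, collapse = ", ")
      ))
    }
    window_costs <- window_costs[wl]
  }
  if (length(window_costs) != 4 || anyNA(window_costs)) {
    abort("incomplete trajectory: all four window costs must be present")
  }
  drop(interp_weight_matrix() %*% as.numeric(window_costs))
}

discount_weights <- function(annual_rate) {
  c(rep(1, 12), rep((1 + annual_rate)^-1, 12), rep((1 + annual_rate)^-2, 9))
}

#' Discount a monthly cost trajectory
#'
#' Applies annual discounting by study year: months 1--12 undiscounted,
#' months 13--24 divided by (1 + rate), months 25--33 divided by
#' (1 + rate)^2. Year boundaries are study years indexed from baseline,
#' not calendar years.
#'
#' @param monthly_costs Numeric vector of 33 monthly costs (pounds).
#' @param annual_rate Annual discount rate as a proportion (default 0.035,
#'   the reference-case rate; 0.015 is the public-health sensitivity rate).
#' @return The discounted total in pounds.
#' @examples
#' m <- numeric(33); m[18] <- 100
#' discount_total(m) # 100 / 1.035
#' @export
discount_total <- function(monthly_costs, annual_rate = 0.035) {
  if (length(monthly_costs) != 33) {
    abort("monthly_costs must have exactly 33 values (months 1-33)")
  }
  if (!is.finite(annual_rate) || annual_rate < 0) {
    abort("annual_rate must be a non-negative proportion")
  }
  sum(monthly_costs * discount_weights(annual_rate))
}

# Per-window weights: contribution of each window cost to the discounted
# 33-month total (collapses interpolation + discounting into four numbers).
window_total_weights <- function(annual_rate) {
  drop(crossprod(interp_weight_matrix(), discount_weights(annual_rate)))
}

#' Price service-use counts for each observed wave
#'
#' Combines individual-level service-use counts with the unit-cost ledger
#' to produce a cost per pupil per observed six-month window, with its
#' decomposition into the education, health and criminal-justice sectors.
#' An item-missing count (`NA`) means the instrument was returned with that
#' field blank and is costed as zero use; a wave with no rows at all is
#' wave-missing and simply yields no row here.
#'
#' @param service_use Long-format data frame with columns `pupil_id`,
#'   `wave`, `service_id`, `count`. `count` may be `NA` (item-missing).
#' @param unit_costs A unit-cost table; defaults to [unit_cost_table()].
#' @return A tibble with one row per (pupil, observed wave): `pupil_id`,
#'   `wave`, `cost`, `education_cost`, `health_cost`, `criminal_cost`.
#'   Sector columns sum to `cost` exactly.
#' @examples
#' use <- tibble::tibble(
#'   pupil_id = "p1", wave = "m7_12",
#'   service_id = c("gp_surgery", "accident_emergency"), count = c(1L, 1L)
#' )
#' cost_waves(use) # 46 + 233 = 279
#' @export
cost_waves <- function(service_use, unit_costs = unit_cost_table()) {
  service_use <- as_tibble(service_use)
  assert_columns(service_use, c("pupil_id", "wave", "service_id", "count"),
                 "service_use")
  unit_costs <- validate_unit_costs(unit_costs)

  unknown <- setdiff(unique(service_use$service_id), unit_costs$service_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown service_id(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  if (any(service_use$count < 0, na.rm = TRUE)) {
    abort("negative service-use counts are not allowed")
  }
  bad_wave <- setdiff(unique(service_use$wave), wave_levels())
  if (length(bad_wave) > 0) {
    abort(sprintf("unknown wave label(s): %s", paste(bad_wave, collapse = ", ")))
  }

  service_use |>
    mutate(count = ifelse(is.na(.data$count), 0, .data$count)) |>
    left_join(unit_costs, by = "service_id") |>
    mutate(item_cost = .data$count * .data$unit_cost) |>
    group_by(.data$pupil_id, .data$wave, .data$sector) |>
    summarise(cost = sum(.data$item_cost), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "sector", values_from = "cost", values_fill = 0,
      names_expand = FALSE
    ) |>
    (\(d) {
      for (s in c("education", "health", "criminal_justice")) {
        if (!s %in% names(d)) d[[s]] <- 0
      }
      d
    })() |>
    mutate(cost = .data$education + .data$health + .data$criminal_justice) |>
    select(
      "pupil_id", "wave", "cost",
      education_cost = "education", health_cost = "health",
      criminal_cost = "criminal_justice"
    ) |>
    arrange(.data$pupil_id, factor(.data$wave, levels = wave_levels()))
}

#' Build the per-pupil 33-month cost dataset
#'
#' Runs the full costing chain for a cohort: prices each observed wave,
#' interpolates monthly rates across the survey gaps, discounts, and flags
#' completeness. A pupil is cost-complete only when all four windows
#' (including pre-baseline, which anchors the interpolation) are observed;
#' incomplete pupils keep `NA` totals and are excluded from complete-case
#' analysis downstream. The pre-baseline window cost is reported separately
#' as `baseline_cost` (undiscounted) and never enters the totals. Sector
#' totals are interpolated and discounted with the same weights, so they
#' sum to the pupil total exactly.
#'
#' @param service_use Long-format service use as in [cost_waves()]. Waves
#'   with no rows for a pupil are treated as wave-missing.
#' @param unit_costs Unit-cost table; defaults to [unit_cost_table()].
#' @param discount_rate Annual discount rate (default 0.035).
#' @param pupil_waves Optional data frame `pupil_id`, `wave`, `wave_missing`
#'   making wave-missingness explicit (e.g. to distinguish a wave observed
#'   with all-zero use from an absent instrument). A wave flagged missing
#'   must have no service-use rows.
#' @return A tibble with one row per pupil: `pupil_id`, `baseline_cost`,
#'   `total_discounted`, `education_cost`, `health_cost`, `criminal_cost`
#'   and `complete`. Totals are `NA` for incomplete pupils.
#' @export
build_cost_dataset <- function(service_use,
                               unit_costs = unit_cost_table(),
                               discount_rate = 0.035,
                               pupil_waves = NULL) {
  service_use <- as_tibble(service_use)
  dup <- service_use |>
    count(.data$pupil_id, .data$wave, .data$service_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate (pupil, wave, service) rows, e.g. pupil %s wave %s",
      dup$pupil_id[1], dup$wave[1]
    ))
  }

  wave_costs <- cost_waves(service_use, unit_costs)

  if (!is.null(pupil_waves)) {
    pupil_waves <- as_tibble(pupil_waves)
    assert_columns(pupil_waves, c("pupil_id", "wave", "wave_missing"),
                   "pupil_waves")
    contradiction <- wave_costs |>
      inner_join(
        filter(pupil_waves, .data$wave_missing),
        by = c("pupil_id", "wave")
      )
    if (nrow(contradiction) > 0) {
      abort(sprintf(
        "wave flagged missing but has service-use rows: pupil %s wave %s",
        contradiction$pupil_id[1], contradiction$wave[1]
      ))
    }
    pupils <- distinct(pupil_waves, .data$pupil_id)
  } else {
    pupils <- distinct(wave_costs, .data$pupil_id)
  }

  # Wide window-cost matrices per sector; absent wave => NA
  wide <- function(col) {
    wave_costs |>
      select("pupil_id", "wave", value = all_of(col)) |>
      tidyr::pivot_wider(names_from = "wave", values_from = "value") |>
      (\(d) {
        for (w in wave_levels()) if (!w %in% names(d)) d[[w]] <- NA_real_
        d
      })() |>
      right_join(pupils, by = "pupil_id") |>
      arrange(.data$pupil_id)
  }

  totals_from <- function(mat, weights, complete) {
    out <- rep(NA_real_, nrow(mat))
    if (any(complete)) {
      out[complete] <- as.matrix(mat[complete, , drop = FALSE]) %*% weights
    }
    out
  }

  w_total <- wide("cost")
  window_mat <- as.matrix(w_total[, wave_levels()])
  complete <- !apply(is.na(window_mat), 1, any)
  weights <- window_total_weights(discount_rate)

  sector_total <- function(col) {
    m <- wide(col)[, wave_levels()]
    totals_from(m, weights, complete)
  }

  tibble(
    pupil_id = w_total$pupil_id,
    baseline_cost = window_mat[, "pre_baseline"],
    total_discounted = totals_from(
      w_total[, wave_levels()], weights, complete
    ),
    education_cost = sector_total("education_cost"),
    health_cost = sector_total("health_cost"),
    criminal_cost = sector_total("criminal_cost"),
    complete = complete
  )
}
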