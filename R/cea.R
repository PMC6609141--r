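# Decision-analytic outputs: dominance classification, CEACs and the
# cost-effectiveness plane.
#
# Conventions (fixed and shared across all three operations):
#   * effect on the x axis, cost on the y axis;
#   * quadrant tie rule: delta_c = 0 belongs to the southern side and
#     delta_e = 0 to the western side;
#   * acceptability uses strict net monetary benefit, lambda * de - dc > 0,
#     so a replicate with NMB exactly 0 counts as not cost-effective.

replicate_pairs <- function(x) {
  if (inherits(x, "incremental_estimates")) x <- x$replicates
  x <- as_tibble(x)
  assert_columns(x, c("delta_c", "delta_e"), "replicates")
  if (nrow(x) == 0) abort("replicates must contain at least one (delta_c, delta_e) pair")
  x
}

quadrant_of <- function(delta_c, delta_e) {
  paste0(
    ifelse(delta_c > 0, "N", "S"),
    ifelse(delta_e > 0, "E", "W")
  )
}

ci_spans_zero <- function(ci) {
  !is.null(ci) && length(ci) == 2 && ci[1] < 0 && ci[2] > 0
}

#' Classify cost-effectiveness by conventional decision rules
#'
#' Places the incremental estimate on the cost-effectiveness plane and
#' applies the conventional dominance rules. In the south-east quadrant
#' (cheaper and more effective) the intervention dominates; dominance is
#' downgraded to *weak* when either confidence interval spans zero. In the
#' north-west it is dominated (again weakly when a CI spans zero). In the
#' north-east and south-west there is a trade-off and the ICER
#' `delta_c / delta_e` is reported. An ICER whose numerator and denominator
#' have opposite signs is negative and carries no meaning, so it is
#' suppressed (`NA`), as it is when `delta_e` is zero.
#'
#' @param delta_c Incremental cost (pounds).
#' @param delta_e Incremental effect (proportion of cases avoided).
#' @param ci_c,ci_e Optional 95% intervals `c(lo, hi)` used for the
#'   weak-dominance downgrade.
#' @return A one-row tibble: `quadrant` (NE/SE/NW/SW), `label` (dominant,
#'   weakly_dominant, dominated, weakly_dominated, trade_off) and `icer`
#'   (pounds per case avoided, `NA` when not reported).
#' @examples
#' classify_dominance(-17.19, 0.08,
#'                    ci_c = c(-402.84, 368.46), ci_e = c(0.06, 0.09))
#' classify_dominance(100, 0.05) # trade-off, ICER 2000
#' @export
classify_dominance <- function(delta_c, delta_e, ci_c = NULL, ci_e = NULL) {
  if (!is.null(ci_c) && ci_c[1] > ci_c[2]) abort("ci_c must be ordered (lo, hi)")
  if (!is.null(ci_e) && ci_e[1] > ci_e[2]) abort("ci_e must be ordered (lo, hi)")

  quadrant <- quadrant_of(delta_c, delta_e)
  weak <- ci_spans_zero(ci_c) || ci_spans_zero(ci_e)
  label <- switch(quadrant,
    SE = if (weak) "weakly_dominant" else "dominant",
    NW = if (weak) "weakly_dominated" else "dominated",
    "trade_off"
  )

  icer <- NA_real_
  if (delta_e == 0) {
    if (delta_c != 0) {
      inform("delta_e is zero: ICER not reported")
      label <- "trade_off"
    }
  } else if (sign(delta_c) == sign(delta_e) && label == "trade_off") {
    icer <- delta_c / delta_e
  }

  tibble(quadrant = quadrant, label = label, icer = icer)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold lambda (pounds per case avoided),
#' the probability that the intervention is cost-effective: the proportion
#' of bootstrap replicates with positive net monetary benefit,
#' `lambda * delta_e - delta_c > 0`. At `lambda = 0` this is the
#' probability of a cost saving, `P(delta_c < 0)`.
#'
#' @param x An `incremental_estimates` object or a data frame of replicate
#'   pairs with columns `delta_c`, `delta_e`.
#' @param lambda_grid Non-negative thresholds in pounds; default 0--2000 in
#'   steps of 5.
#' @return A tibble of class `ceac_curve` with columns `lambda` and
#'   `probability`.
#' @examples
#' reps <- tibble::tibble(delta_c = c(5, -5, 5), delta_e = c(0.1, 0.1, -0.1))
#' ceac(reps, lambda_grid = c(0, 100)) # 1/3 then 2/3
#' @export
ceac <- function(x, lambda_grid = seq(0, 2000, by = 5)) {
  reps <- replicate_pairs(x)
  if (any(lambda_grid < 0)) abort("lambda values must be non-negative")
  probability <- vapply(
    lambda_grid,
    function(l) mean(l * reps$delta_e - reps$delta_c > 0),
    numeric(1)
  )
  structure(
    tibble(lambda = as.numeric(lambda_grid), probability = probability),
    class = c("ceac_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Summarise the cost-effectiveness plane
#'
#' Assigns every bootstrap replicate to a quadrant of the CE plane (effect
#' on x, cost on y) under the fixed tie rule (`delta_c = 0` south,
#' `delta_e = 0` west) and returns the quadrant proportions together with
#' the replicate scatter for plotting.
#'
#' @inheritParams ceac
#' @return An object of class `ce_plane`: list with `proportions` (tibble
#'   `quadrant`, `proportion` over NE, SE, NW, SW, summing to 1) and
#'   `replicates` (tibble `delta_e`, `delta_c`, `quadrant`).
#' @export
ce_plane_summary <- function(x) {
  reps <- replicate_pairs(x)
  reps <- mutate(reps, quadrant = quadrant_of(.data$delta_c, .data$delta_e))
  props <- tibble(quadrant = c("NE", "SE", "NW", "SW")) |>
    left_join(
      count(reps, .data$quadrant) |>
        mutate(proportion = .data$n / sum(.data$n)) |>
        select("quadrant", "proportion"),
      by = "quadrant"
    ) |>
    mutate(proportion = dplyr::coalesce(.data$proportion, 0))
  structure(
    list(
      proportions = props,
      replicates = select(reps, "delta_e", "delta_c", "quadrant")
    ),
    class = "ce_plane"
  )
}

#' @export
print.ce_plane <- function(x, ...) {
  cat("<ce_plane> quadrant proportions:\n")
  print(x$proportions)
  invisible(x)
}

# Plotting ---------------------------------------------------------------------

#' Plot the cost-effectiveness plane
#'
#' Scatter of bootstrap replicate pairs (effect on x, incremental cost on
#' y) with the axes drawn through the origin.
#'
#' @param x An `incremental_estimates` object, `ce_plane` object or
#'   replicate data frame.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(x) {
  reps <- if (inherits(x, "ce_plane")) x$replicates else {
    ce_plane_summary(x)$replicates
  }
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$delta_e, y = .data$delta_c)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8, colour = "steelblue4") +
    ggplot2::labs(
      x = "Incremental effect (proportion of heavy-drinking cases avoided)",
      y = "Incremental cost (£)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A `ceac_curve` tibble (or anything [ceac()] accepts, in which
#'   case the curve is computed with the default grid).
#' @param ... Passed to [ceac()] when `x` is not already a curve.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, ...) {
  curve <- if (inherits(x, "ceac_curve")) x else ceac(x, ...)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lambda, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (£ per heavy-drinking case avoided)",
      y = "Probability cost-effective"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.incremental_estimates <- function(object, ...) plot_ce_plane(object)

#' @export
autoplot.ceac_curve <- function(object, ...) plot_ceac(object)

#' @export
autoplot.ce_plane <- function(object, ...) plot_ce_plane(object)
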