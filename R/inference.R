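# Inference: covariate-adjusted incremental cost and effect, with
# cluster-respecting uncertainty from a school-level bootstrap.
#
# The estimand on each scale is the arm coefficient of a linear model:
#   cost:   total_cost ~ arm + location + fsm_band + school_type +
#           baseline_cost, school random intercept
#   effect: hed33 ~ arm + location + fsm_band + school_type + baseline_hed,
#           linear-probability model, school random intercept
# so the effect arm coefficient *is* the adjusted risk difference; it is
# reported control-minus-intervention (positive = cases avoided).

arm_levels <- function() c("control", "intervention")

normalise_arm <- function(data) {
  arm <- as.character(data$arm)
  bad <- setdiff(unique(arm), arm_levels())
  if (length(bad) > 0) {
    abort(sprintf("arm must be one of control/intervention, got: %s",
                  paste(bad, collapse = ", ")))
  }
  data$arm <- factor(arm, levels = arm_levels())
  data
}

check_design <- function(data) {
  tab <- data |>
    distinct(.data$school_id, .data$arm) |>
    count(.data$arm)
  if (nrow(tab) < 2 || any(tab$n < 2)) {
    abort("degenerate design: need at least 2 schools in each arm")
  }
  invisible(data)
}

# Keep only covariates that actually vary in this dataset; a factor with a
# single observed level would otherwise break the contrasts.
varying_terms <- function(data, terms) {
  terms[vapply(terms, function(v) dplyr::n_distinct(data[[v]]) > 1, logical(1))]
}

model_formula <- function(response, data, adjusted, covars, random = TRUE) {
  rhs <- "arm"
  if (adjusted) {
    keep <- varying_terms(data, covars)
    if (length(keep) > 0) rhs <- paste(c(rhs, keep), collapse = " + ")
  }
  if (random) rhs <- paste(rhs, "+ (1 | school_id)")
  as.formula(paste(response, "~", rhs))
}

quiet_lmer <- function(formula, data) {
  withCallingHandlers(
    suppressMessages(lme4::lmer(
      formula, data = data, REML = TRUE,
      control = lme4::lmerControl(
        calc.derivs = FALSE,
        check.conv.singular = "ignore"
      )
    )),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

# Fit one arm-coefficient model; returns the coefficient and its SE.
# engine "lmer" falls back to the fixed-effects fit if the mixed model
# errors out (kept so every bootstrap replicate yields an estimate).
fit_arm_model <- function(data, response, covars, adjusted, engine) {
  fixed <- model_formula(response, data, adjusted, covars, random = FALSE)
  used <- engine
  fit <- NULL
  if (engine == "lmer") {
    mixed <- model_formula(response, data, adjusted, covars, random = TRUE)
    fit <- tryCatch(quiet_lmer(mixed, data), error = function(e) NULL)
    if (is.null(fit)) {
      warn("mixed-model fit failed; falling back to the fixed-effects model")
      used <- "lm"
    }
  }
  if (is.null(fit)) fit <- lm(fixed, data = data)

  cf <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  term <- "armintervention"
  if (!term %in% names(cf) || is.na(cf[[term]])) {
    abort("degenerate design: arm effect is not estimable (singular design)")
  }
  se <- tryCatch(
    suppressWarnings(sqrt(as.matrix(vcov(fit))[term, term])),
    error = function(e) NA_real_ # degenerate vcov (e.g. zero residual variance)
  )
  list(
    coef = unname(cf[[term]]),
    se = se,
    fit = fit,
    engine_used = used
  )
}

#' Estimate the incremental cost
#'
#' Fits the cost model on complete-case data and returns the adjusted
#' between-arm difference in total cost (intervention minus control, in
#' pounds; negative = cost saving).
#'
#' @param data Analysis data frame with columns `school_id`, `arm`,
#'   `location`, `fsm_band`, `school_type`, `baseline_cost`, `total_cost`.
#'   Rows with missing `total_cost` are dropped.
#' @param adjusted If `TRUE` (default) adjust for location, FSM band,
#'   school type and baseline cost; if `FALSE`, arm only (the cluster-only
#'   sensitivity model). Clustering is respected either way.
#' @param engine `"lmer"` (default) for the school random-intercept model,
#'   `"lm"` for the fixed-effects fit used inside the fast bootstrap path.
#' @return An object of class `cea_fit`: list with `delta` (the incremental
#'   cost), `se`, `term`, `n`, `engine_used` and the underlying `fit`.
#' @seealso [fit_effect_model()], [cluster_bootstrap()]
#' @export
fit_cost_model <- function(data, adjusted = TRUE, engine = c("lmer", "lm")) {
  engine <- match.arg(engine)
  data <- normalise_arm(as_tibble(data))
  assert_columns(data, c("school_id", "total_cost"), "analysis data")
  data <- filter(data, !is.na(.data$total_cost))
  check_design(data)
  res <- fit_arm_model(
    data, "total_cost",
    covars = c("location", "fsm_band", "school_type", "baseline_cost"),
    adjusted = adjusted, engine = engine
  )
  structure(
    list(
      outcome = "cost", term = "incremental_cost",
      delta = res$coef, se = res$se, n = nrow(data),
      adjusted = adjusted, engine_used = res$engine_used, fit = res$fit
    ),
    class = "cea_fit"
  )
}

#' Estimate the incremental effect
#'
#' Fits a linear-probability model for the binary 33-month heavy-episodic-
#' drinking outcome and returns the adjusted risk difference, reported
#' control minus intervention so that a positive value means cases avoided
#' by the intervention.
#'
#' @inheritParams fit_cost_model
#' @param data As [fit_cost_model()] but with `baseline_hed` and the binary
#'   outcome `hed33` (0/1). Rows with missing `hed33` are dropped.
#' @return An object of class `cea_fit` with `delta` = the proportion of
#'   cases avoided.
#' @export
fit_effect_model <- function(data, adjusted = TRUE, engine = c("lmer", "lm")) {
  engine <- match.arg(engine)
  data <- normalise_arm(as_tibble(data))
  assert_columns(data, c("school_id", "hed33"), "analysis data")
  data <- filter(data, !is.na(.data$hed33))
  if (!all(data$hed33 %in% c(0, 1))) {
    abort("hed33 must be binary 0/1")
  }
  check_design(data)
  res <- fit_arm_model(
    data, "hed33",
    covars = c("location", "fsm_band", "school_type", "baseline_hed"),
    adjusted = adjusted, engine = engine
  )
  structure(
    list(
      outcome = "effect", term = "cases_avoided",
      delta = -res$coef, se = res$se, n = nrow(data),
      adjusted = adjusted, engine_used = res$engine_used, fit = res$fit
    ),
    class = "cea_fit"
  )
}

#' @export
print.cea_fit <- function(x, ...) {
  cat(sprintf(
    "<cea_fit> %s: delta = %.4f (se %.4f), n = %d, %s, engine = %s\n",
    x$term, x$delta, x$se, x$n,
    if (x$adjusted) "adjusted" else "cluster only", x$engine_used
  ))
  invisible(x)
}

# Fast fixed-effects refit machinery: design matrices are built once on the
# full complete-case data (so factor codings are stable across replicates)
# and each school resample is a row-index subset.
bootstrap_engine_lm <- function(data, adjusted, B, max_retries) {
  prep <- function(response, covars) {
    d <- filter(data, !is.na(.data[[response]]))
    f <- model_formula(response, d, adjusted, covars, random = FALSE)
    X <- model.matrix(f, d)
    list(
      X = X, y = d[[response]], school = as.character(d$school_id),
      arm_col = match("armintervention", colnames(X))
    )
  }
  mc <- prep("total_cost", c("location", "fsm_band", "school_type", "baseline_cost"))
  me <- prep("hed33", c("location", "fsm_band", "school_type", "baseline_hed"))

  schools <- data |> distinct(.data$school_id, .data$arm)
  by_arm <- split(as.character(schools$school_id), schools$arm)
  idx_c <- split(seq_along(mc$y), mc$school)
  idx_e <- split(seq_along(me$y), me$school)

  one_fit <- function(m, idx) {
    fit <- lm.fit(m$X[idx, , drop = FALSE], m$y[idx])
    cf <- fit$coefficients[m$arm_col]
    if (is.na(cf)) NA_real_ else unname(cf)
  }

  replicates <- matrix(NA_real_, nrow = B, ncol = 2)
  retries_exhausted <- FALSE
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      draw <- unlist(lapply(by_arm, function(s) {
        sample(s, length(s), replace = TRUE)
      }), use.names = FALSE)
      ic <- unlist(idx_c[draw], use.names = FALSE)
      ie <- unlist(idx_e[draw], use.names = FALSE)
      dc <- one_fit(mc, ic)
      de <- one_fit(me, ie)
      if (!is.na(dc) && !is.na(de)) {
        replicates[b, ] <- c(dc, -de)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      retries_exhausted <- TRUE
      break
    }
  }
  if (retries_exhausted) {
    abort(sprintf(
      "bootstrap replicate remained degenerate after %d redraws", max_retries
    ))
  }
  replicates
}

bootstrap_engine_lmer <- function(data, adjusted, B, max_retries) {
  schools <- data |> distinct(.data$school_id, .data$arm)
  by_arm <- split(as.character(schools$school_id), schools$arm)
  rows <- split(seq_len(nrow(data)), as.character(data$school_id))

  replicates <- matrix(NA_real_, nrow = B, ncol = 2)
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      draw <- unlist(lapply(by_arm, function(s) {
        sample(s, length(s), replace = TRUE)
      }), use.names = FALSE)
      resampled <- data[unlist(rows[draw], use.names = FALSE), ]
      # resampled copies of a school are distinct clusters
      resampled$school_id <- rep(
        paste0(draw, "#", seq_along(draw)),
        vapply(rows[draw], length, integer(1))
      )
      est <- tryCatch({
        dc <- fit_cost_model(resampled, adjusted = adjusted, engine = "lmer")
        de <- fit_effect_model(resampled, adjusted = adjusted, engine = "lmer")
        c(dc$delta, de$delta)
      }, error = function(e) NULL)
      if (!is.null(est)) {
        replicates[b, ] <- est
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "bootstrap replicate remained degenerate after %d redraws", max_retries
      ))
    }
  }
  replicates
}

#' Cluster bootstrap of incremental cost and effect
#'
#' Resamples schools (the randomisation and cluster unit) with replacement,
#' stratified by arm so each resample has the observed number of schools
#' per arm, and refits both arm-coefficient models jointly on each
#' resample; the replicate pairs therefore preserve the cost--effect
#' correlation. Confidence intervals are the 2.5th and 97.5th percentiles
#' of the replicates. Point estimates come from the mixed models
#' ([fit_cost_model()] / [fit_effect_model()]); replicate refits default to
#' the fixed-effects engine, which estimates the same arm contrast while
#' the school resampling itself carries the cluster structure (pass
#' `engine = "lmer"` to refit the random-intercept models per replicate).
#' A replicate whose design turns degenerate (e.g. a stratum vanishing) is
#' redrawn, up to `max_retries` times.
#'
#' @inheritParams fit_cost_model
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the run is deterministic given `seed`.
#' @param engine Engine for the replicate refits: `"lm"` (default) or
#'   `"lmer"`.
#' @param max_retries Redraw cap per replicate before erroring.
#' @return An object of class `incremental_estimates`: `delta_c`,
#'   `delta_e`, `ci_c`, `ci_e` (95% percentile), `replicates` (tibble with
#'   `rep`, `delta_c`, `delta_e`), `B`, `seed`, plus fit metadata. Methods:
#'   `print()`, `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' \donttest{
#' sim <- simulate_trial(trial_config(n_schools = 12, pupils_per_school = 40),
#'                       seed = 7)
#' dat <- analysis_dataset(sim)
#' est <- cluster_bootstrap(dat, B = 50, seed = 1)
#' tidy(est)
#' }
#' @export
cluster_bootstrap <- function(data, B = 1000, seed = 1L, adjusted = TRUE,
                              engine = c("lm", "lmer"), max_retries = 25L) {
  engine <- match.arg(engine)
  if (B < 1) abort("B must be at least 1")
  data <- normalise_arm(as_tibble(data))
  assert_columns(
    data, c("school_id", "arm", "total_cost", "hed33"), "analysis data"
  )
  # complete-case rows for each model handled inside; bootstrap uses rows
  # with both observed so the joint resample is well defined
  data <- filter(data, !is.na(.data$total_cost), !is.na(.data$hed33))
  check_design(data)

  point_c <- fit_cost_model(data, adjusted = adjusted, engine = "lmer")
  point_e <- fit_effect_model(data, adjusted = adjusted, engine = "lmer")

  replicates <- with_seed(seed, {
    if (engine == "lm") {
      bootstrap_engine_lm(data, adjusted, B, max_retries)
    } else {
      bootstrap_engine_lmer(data, adjusted, B, max_retries)
    }
  })

  n_arm <- data |> count(.data$arm)
  structure(
    list(
      delta_c = point_c$delta,
      delta_e = point_e$delta,
      se_c = point_c$se,
      se_e = point_e$se,
      ci_c = unname(quantile(replicates[, 1], c(0.025, 0.975))),
      ci_e = unname(quantile(replicates[, 2], c(0.025, 0.975))),
      replicates = tibble(
        rep = seq_len(B),
        delta_c = replicates[, 1],
        delta_e = replicates[, 2]
      ),
      B = B, seed = seed, adjusted = adjusted, engine = engine,
      n = nrow(data),
      n_intervention = n_arm$n[n_arm$arm == "intervention"],
      n_control = n_arm$n[n_arm$arm == "control"],
      n_schools = dplyr::n_distinct(data$school_id)
    ),
    class = "incremental_estimates"
  )
}

#' @export
print.incremental_estimates <- function(x, ...) {
  cat("<incremental_estimates>\n")
  cat(sprintf("  incremental cost  : %s\n",
              fmt_ci(x$delta_c, x$ci_c[1], x$ci_c[2])))
  cat(sprintf("  cases avoided     : %s\n",
              fmt_ci(x$delta_e, x$ci_e[1], x$ci_e[2])))
  cat(sprintf("  %d bootstrap resamples of %d schools (seed %s), %s\n",
              x$B, x$n_schools, format(x$seed),
              if (x$adjusted) "adjusted" else "cluster only"))
  invisible(x)
}

#' @rdname cluster_bootstrap
#' @param x An `incremental_estimates` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.incremental_estimates <- function(x, ...) {
  tibble(
    term = c("incremental_cost", "cases_avoided"),
    estimate = c(x$delta_c, x$delta_e),
    conf.low = c(x$ci_c[1], x$ci_e[1]),
    conf.high = c(x$ci_c[2], x$ci_e[2])
  )
}

#' @rdname cluster_bootstrap
#' @exportS3Method generics::glance
glance.incremental_estimates <- function(x, ...) {
  tibble(
    n = x$n, n_intervention = x$n_intervention, n_control = x$n_control,
    n_schools = x$n_schools, B = x$B, seed = x$seed,
    adjusted = x$adjusted, engine = x$engine
  )
}
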