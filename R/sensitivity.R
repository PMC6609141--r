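# One-way sensitivity analyses: multiple imputation by chained equations
# (predictive mean matching for costs, a logit model for the binary
# outcome, Rubin's rules for pooling), a lower discount rate, cluster-only
# adjustment, and +/-5% cost perturbations.
#
# The chained-equations engine is implemented here: at each cycle every
# incomplete variable is regressed on the others (plus the fully observed
# covariates), parameters are perturbed by a proper posterior draw, and
# missing entries are refilled -- by donor matching (PMM, k nearest by
# predicted mean) for continuous variables and by Bernoulli draws from a
# logistic model for binary ones.

mi_predictors <- function(data, impute_vars) {
  fixed <- intersect(
    c("arm", "baseline_cost", "baseline_hed", "location", "fsm_band",
      "school_type"),
    names(data)
  )
  list(fixed = fixed, impute = impute_vars)
}

# Design matrix for one imputation model: everything except the target.
mi_design <- function(data, target, preds) {
  rhs <- setdiff(c(preds$fixed, preds$impute), target)
  rhs <- rhs[vapply(rhs, function(v) dplyr::n_distinct(data[[v]]) > 1, logical(1))]
  if (length(rhs) == 0) rhs <- "1"
  f <- as.formula(paste("~", paste(rhs, collapse = " + ")))
  model.matrix(f, data)
}

# One PMM update: proper draw of (beta, sigma), predicted means for donors
# with beta-hat and for recipients with the drawn beta, then sample one of
# the k nearest donors' observed values.
pmm_draw <- function(y, X, miss, k = 5) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  qr_fit <- lm.fit(Xo, yo)
  keep <- !is.na(qr_fit$coefficients)
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  fit <- lm.fit(Xo, yo)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(length(yo) - length(beta), 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  beta_star <- beta + drop(chol(sigma2 * XtXinv) %*% rnorm(length(beta)))
  yhat_obs <- drop(Xo %*% beta)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(p) {
    d <- abs(yhat_obs - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    yo[sample(donors, 1)]
  }, numeric(1))
}

# One logistic update with a normal posterior draw of the coefficients.
logit_draw <- function(y, X, miss) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  fit <- suppressWarnings(glm.fit(Xo, yo, family = binomial()))
  beta <- fit$coefficients
  ok <- !is.na(beta)
  w <- fit$weights
  V <- tryCatch(
    chol2inv(chol(crossprod(Xo[, ok, drop = FALSE] * sqrt(w)) +
                    diag(1e-8, sum(ok)))),
    error = function(e) diag(1e-4, sum(ok))
  )
  beta_star <- beta[ok] + drop(chol(V) %*% rnorm(sum(ok)))
  eta <- drop(X[miss, ok, drop = FALSE] %*% beta_star)
  rbinom(length(eta), 1, plogis(eta))
}

#' Multiple imputation by chained equations
#'
#' Fills missing cost and outcome variables by cycling single-variable
#' imputation models: predictive mean matching (k = 5 donors, proper
#' posterior draws) for continuous cost variables and a logistic model for
#' binary variables. By default the variables imputed are `total_cost`,
#' `hed33`, and the auxiliaries `baseline_cost` (the pre-baseline window
#' cost) and `hed12` (interim drinking) where present with missing values;
#' predictors are the treatment arm, baseline cost and drinking, school
#' location, FSM band and school type, plus the other imputation targets.
#' Deterministic given `seed`. A dataset with no missing values is
#' returned unchanged (m identical copies).
#'
#' @param data Pupil-level analysis data frame.
#' @param m Number of imputed datasets (default 5).
#' @param seed Integer seed.
#' @param cycles Chained-equation cycles per imputation (default 10).
#' @param k PMM donor-pool size (default 5).
#' @param impute_vars Variables to impute; defaults to those among
#'   `baseline_cost`, `hed12`, `total_cost`, `hed33` that contain `NA`.
#' @return A list of `m` completed tibbles, with attribute `"imputed"`
#'   naming the variables imputed.
#' @export
impute_mice <- function(data, m = 5, seed = 1L, cycles = 10, k = 5,
                        impute_vars = NULL) {
  if (m < 2) abort("m must be at least 2 for multiple imputation")
  data <- as_tibble(data)
  candidates <- intersect(
    c("baseline_cost", "hed12", "total_cost", "hed33"), names(data)
  )
  impute_vars <- impute_vars %||%
    candidates[vapply(candidates, function(v) anyNA(data[[v]]), logical(1))]

  if (length(impute_vars) == 0) {
    out <- rep(list(data), m)
    attr(out, "imputed") <- character()
    return(out)
  }
  for (v in impute_vars) {
    if (all(is.na(data[[v]]))) {
      abort(sprintf("cannot impute '%s': no observed values", v))
    }
  }
  binary <- vapply(
    impute_vars,
    function(v) all(data[[v]] %in% c(0, 1, NA)),
    logical(1)
  )
  preds <- mi_predictors(data, impute_vars)
  miss_idx <- lapply(data[impute_vars], is.na)

  with_seed(seed, {
    lapply(seq_len(m), function(imp) {
      work <- data
      # initial fill: random draws from the observed values
      for (v in impute_vars) {
        mi <- miss_idx[[v]]
        work[[v]][mi] <- sample(data[[v]][!mi], sum(mi), replace = TRUE)
      }
      for (cyc in seq_len(cycles)) {
        for (v in impute_vars) {
          mi <- miss_idx[[v]]
          if (!any(mi)) next
          X <- mi_design(work, v, preds)
          y <- work[[v]]
          y[mi] <- NA
          work[[v]][mi] <- if (binary[[v]]) {
            logit_draw(y, X, mi)
          } else {
            pmm_draw(y, X, mi, k = k)
          }
        }
      }
      work
    }) |>
      (\(l) { attr(l, "imputed") <- impute_vars; l })()
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is the mean within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance. The confidence
#' interval uses the t distribution with the classical Rubin degrees of
#' freedom.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation squared standard
#'   errors, same length.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `within`, `between`, `variance`,
#'   `conf.low`, `conf.high`, `df`, `m`.
#' @examples
#' pool_rubin(c(1, 2, 3), c(1, 1, 1)) # estimate 2, variance 2.333...
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  if (length(estimates) != length(variances)) {
    abort("estimates and variances must have the same length")
  }
  m <- length(estimates)
  if (m < 2) abort("pooling requires at least 2 imputations")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  half <- qt(1 - (1 - conf_level) / 2, df) * sqrt(total)
  tibble(
    estimate = qbar, within = W, between = B, variance = total,
    conf.low = qbar - half, conf.high = qbar + half, df = df, m = m
  )
}

sensitivity_variants <- function() {
  c("complete_case_primary", "multiple_imputation", "discount_1_5",
    "cluster_only", "costs_up_5", "costs_down_5")
}

#' Run one sensitivity-analysis variant
#'
#' Re-runs the cost-effectiveness analysis under one of the configurable
#' variants:
#' \describe{
#'   \item{`complete_case_primary`}{the primary analysis (3.5% discount,
#'     full covariate adjustment, complete cases).}
#'   \item{`multiple_imputation`}{imputes missing costs and outcomes by
#'     chained equations ([impute_mice()]), analyses each completed
#'     dataset with the mixed models and pools by Rubin's rules
#'     ([pool_rubin()]); all pupils contribute.}
#'   \item{`discount_1_5`}{re-runs costing at a 1.5% discount rate and
#'     discounts the 33-month outcome by (1.015)^-2 (realised in study
#'     year 3).}
#'   \item{`cluster_only`}{drops the baseline covariates from both models
#'     but keeps the school-level clustering.}
#'   \item{`costs_up_5` / `costs_down_5`}{multiply every pupil's total
#'     cost (including the programme cost) by 1.05 / 0.95 before
#'     modelling; effects are untouched.}
#' }
#'
#' @param sim A `trial_simulation` (or compatible list with `pupils`,
#'   `schools`, `service_use`, `pupil_waves`).
#' @param variant One of [sensitivity_variants()].
#' @param B Bootstrap resamples for the bootstrap-based variants.
#' @param seed Integer seed.
#' @param m Imputations for the MI variant.
#' @param programme_per_pupil Per-pupil programme cost added to the
#'   intervention arm (default the full-scenario figure, rounded as
#'   reported).
#' @param unit_costs Unit-cost table.
#' @param engine Bootstrap replicate engine, see [cluster_bootstrap()].
#' @return A one-row tibble shaped like a results-table row: `variant`,
#'   `n_intervention`, `n_control`, `delta_c`, `ci_c_lo`, `ci_c_hi`,
#'   `delta_e`, `ci_e_lo`, `ci_e_hi`, plus a `ceac` list-column (a
#'   `ceac_curve`, or `NULL` for the MI variant).
#' @export
run_variant <- function(sim,
                        variant = "complete_case_primary",
                        B = 1000, seed = 1L, m = 5,
                        programme_per_pupil = round(programme_cost()$per_pupil),
                        unit_costs = unit_cost_table(),
                        engine = "lm") {
  if (!variant %in% sensitivity_variants()) {
    abort(sprintf("unknown variant '%s'", variant))
  }
  rate <- if (variant == "discount_1_5") 0.015 else 0.035
  adjusted <- variant != "cluster_only"
  cost_scale <- switch(variant, costs_up_5 = 1.05, costs_down_5 = 0.95, 1)
  effect_discount <- if (variant == "discount_1_5") (1.015)^-2 else 1

  dat <- analysis_dataset(sim, unit_costs = unit_costs, discount_rate = rate) |>
    add_programme_cost(programme_per_pupil)

  if (variant == "multiple_imputation") {
    completed <- impute_mice(dat, m = m, seed = seed)
    fits <- lapply(completed, function(d) {
      list(
        c = fit_cost_model(d, adjusted = TRUE),
        e = fit_effect_model(d, adjusted = TRUE)
      )
    })
    pc <- pool_rubin(
      vapply(fits, function(f) f$c$delta, numeric(1)),
      vapply(fits, function(f) f$c$se^2, numeric(1))
    )
    pe <- pool_rubin(
      vapply(fits, function(f) f$e$delta, numeric(1)),
      vapply(fits, function(f) f$e$se^2, numeric(1))
    )
    n_arm <- count(dat, .data$arm)
    return(tibble(
      variant = variant,
      n_intervention = n_arm$n[n_arm$arm == "intervention"],
      n_control = n_arm$n[n_arm$arm == "control"],
      delta_c = pc$estimate, ci_c_lo = pc$conf.low, ci_c_hi = pc$conf.high,
      delta_e = pe$estimate, ci_e_lo = pe$conf.low, ci_e_hi = pe$conf.high,
      ceac = list(NULL)
    ))
  }

  cc <- filter(dat, .data$complete)
  cc <- mutate(cc, total_cost = .data$total_cost * cost_scale)
  est <- cluster_bootstrap(cc, B = B, seed = seed, adjusted = adjusted,
                           engine = engine)
  curve <- ceac(est)

  tibble(
    variant = variant,
    n_intervention = est$n_intervention,
    n_control = est$n_control,
    delta_c = est$delta_c,
    ci_c_lo = est$ci_c[1], ci_c_hi = est$ci_c[2],
    delta_e = est$delta_e * effect_discount,
    ci_e_lo = est$ci_e[1] * effect_discount,
    ci_e_hi = est$ci_e[2] * effect_discount,
    ceac = list(curve)
  )
}

#' Run a set of sensitivity variants
#'
#' Maps [run_variant()] over the requested variants and binds the rows
#' into a results table.
#'
#' @inheritParams run_variant
#' @param variants Character vector of variant names; defaults to all of
#'   [sensitivity_variants()].
#' @return A tibble with one row per variant.
#' @export
run_sensitivity <- function(sim, variants = sensitivity_variants(),
                            B = 1000, seed = 1L, m = 5,
                            programme_per_pupil = round(programme_cost()$per_pupil),
                            unit_costs = unit_cost_table(),
                            engine = "lm") {
  purrr::map(variants, function(v) {
    inform(sprintf("sensitivity: running variant '%s'", v))
    run_variant(sim, v, B = B, seed = seed, m = m,
                programme_per_pupil = programme_per_pupil,
                unit_costs = unit_costs, engine = engine)
  }) |>
    purrr::list_rbind()
}
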