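# End-to-end orchestration: simulate (or load) -> cost -> programme cost ->
# inference -> decision outputs -> optional sensitivity analyses, with
# stage-level logging of record counts and a run manifest for provenance.

#' Pipeline configuration
#'
#' A single structured configuration for [run_pipeline()]; every field can
#' also be set from a YAML file via [read_pipeline_config()]. CLI flags of
#' the shipped `trialcea` script override file values.
#'
#' @param trial A [trial_config()] for the synthetic-data stage.
#' @param B Bootstrap resamples.
#' @param adjusted Adjust for baseline covariates (the primary analysis)?
#' @param engine Bootstrap replicate engine (`"lm"` or `"lmer"`).
#' @param lambda_grid Willingness-to-pay grid for the CEAC (pounds).
#' @param scenario Programme-cost scenario, see [programme_cost()].
#' @param variants Sensitivity variants to run (empty = none).
#' @param m Imputations for the MI variant.
#' @param discount_rate Annual discount rate for pupil costs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trial = trial_config(),
                            B = 1000,
                            adjusted = TRUE,
                            engine = "lm",
                            lambda_grid = seq(0, 2000, by = 5),
                            scenario = "full",
                            variants = character(),
                            m = 5,
                            discount_rate = 0.035) {
  structure(
    list(
      trial = trial, B = B, adjusted = adjusted, engine = engine,
      lambda_grid = lambda_grid, scenario = scenario, variants = variants,
      m = m, discount_rate = discount_rate
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] (with `trial:` holding [trial_config()] arguments
#' and `trial: missingness:` holding [missingness_config()] arguments).
#' Unknown keys are rejected; anything omitted keeps its default.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  trial_args <- raw$trial %||% list()
  if (!is.null(trial_args$missingness)) {
    trial_args$missingness <- do.call(missingness_config, trial_args$missingness)
  }
  check_keys <- function(args, fn, what) {
    unknown <- setdiff(names(args), names(formals(fn)))
    if (length(unknown) > 0) {
      abort(sprintf("unknown %s key(s): %s", what,
                    paste(unknown, collapse = ", ")))
    }
  }
  check_keys(trial_args, trial_config, "trial config")
  trial <- do.call(trial_config, trial_args)
  top <- raw[setdiff(names(raw), "trial")]
  check_keys(top, pipeline_config, "pipeline config")
  do.call(pipeline_config, c(list(trial = trial), top))
}

#' Run the full cost-effectiveness pipeline
#'
#' Executes the stages end to end on simulated data: generation, costing
#' (with complete-case accounting), programme costing, cluster-bootstrap
#' incremental estimates, dominance classification, CE plane and CEAC,
#' and any requested sensitivity variants. When `out_dir` is given the
#' standard output files are written: `costs.csv`, `estimates.json`,
#' `ceac.csv`, `plane.csv`, `sensitivity_results.csv` (if variants were
#' run) and `manifest.json`. `estimates.json` is byte-identical across
#' runs with the same configuration and seed; timestamps live only in the
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed driving every random stage.
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `cea_results`: `simulation`, `data` (analysis
#'   dataset with programme cost added), `programme`, `estimates`
#'   (`incremental_estimates`), `dominance`, `plane`, `ceac`,
#'   `sensitivity` (tibble or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  inform("stage simulate: generating trial data")
  sim <- simulate_trial(config$trial, seed = seed)
  inform(sprintf("stage simulate: %d schools, %d pupils",
                 nrow(sim$schools), nrow(sim$pupils)))

  inform("stage cost: pricing, interpolating and discounting service use")
  programme <- programme_cost(scenario = config$scenario)
  per_pupil <- round(programme$per_pupil)
  dat <- analysis_dataset(sim, discount_rate = config$discount_rate) |>
    add_programme_cost(per_pupil)
  cc <- filter(dat, .data$complete)
  inform(sprintf(
    "stage cost: %d pupils in, %d complete cases kept, %d excluded",
    nrow(dat), nrow(cc), nrow(dat) - nrow(cc)
  ))

  inform(sprintf("stage analyze: cluster bootstrap, B = %d", config$B))
  est <- cluster_bootstrap(
    cc, B = config$B, seed = seed,
    adjusted = config$adjusted, engine = config$engine
  )
  dominance <- classify_dominance(est$delta_c, est$delta_e, est$ci_c, est$ci_e)
  plane <- ce_plane_summary(est)
  curve <- ceac(est, lambda_grid = config$lambda_grid)

  sens <- NULL
  if (length(config$variants) > 0) {
    inform("stage sensitivity")
    sens <- run_sensitivity(
      sim, variants = config$variants, B = config$B, seed = seed,
      m = config$m, programme_per_pupil = per_pupil, engine = config$engine
    )
  }

  manifest <- list(
    package = "trialcea",
    version = as.character(packageVersion("trialcea")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    scenario = config$scenario,
    B = config$B,
    adjusted = config$adjusted,
    engine = config$engine,
    discount_rate = config$discount_rate,
    n_schools = nrow(sim$schools),
    n_pupils = nrow(sim$pupils),
    n_complete = nrow(cc)
  )

  results <- structure(
    list(
      simulation = sim, data = dat, programme = programme,
      estimates = est, dominance = dominance, plane = plane, ceac = curve,
      sensitivity = sens, manifest = manifest
    ),
    class = "cea_results"
  )
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' @export
print.cea_results <- function(x, ...) {
  cat("<cea_results>\n")
  print(x$estimates)
  cat(sprintf("  decision: %s (%s quadrant)\n",
              x$dominance$label, x$dominance$quadrant))
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' @param results A `cea_results` object.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  costs <- results$data |>
    select(any_of(c(
      "pupil_id", "baseline_cost", "total_cost", "education_cost",
      "health_cost", "criminal_cost", "complete"
    )))
  utils::write.csv(costs, p("costs.csv"), row.names = FALSE)

  est <- results$estimates
  jsonlite::write_json(
    list(
      delta_c = est$delta_c, delta_e = est$delta_e,
      ci_c = est$ci_c, ci_e = est$ci_e,
      B = est$B, seed = est$seed,
      n_intervention = est$n_intervention, n_control = est$n_control,
      dominance = as.list(results$dominance)
    ),
    p("estimates.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(results$ceac, p("ceac.csv"), row.names = FALSE)
  utils::write.csv(results$plane$replicates, p("plane.csv"), row.names = FALSE)
  if (!is.null(results$sensitivity)) {
    utils::write.csv(
      select(results$sensitivity, -"ceac"),
      p("sensitivity_results.csv"), row.names = FALSE
    )
  }
  jsonlite::write_json(results$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Report rendering -------------------------------------------------------------

#' Render the programme-cost table
#'
#' Formats the delivery ledger as the standard report table: component
#' rows, stage subtotals, the total, and per-school / per-pupil means, all
#' rounded to whole pounds (component amounts are integers already).
#'
#' @inheritParams programme_cost
#' @return A tibble with columns `item` and `amount_gbp` (whole pounds).
#' @examples
#' render_table_programme()
#' @export
render_table_programme <- function(ledger = programme_ledger(),
                                   scenario = "full",
                                   n_schools = attr(ledger, "n_schools"),
                                   n_pupils = attr(ledger, "n_pupils")) {
  agg <- programme_cost(ledger, scenario, n_schools, n_pupils)
  kept <- switch(scenario,
    full = ledger,
    no_parental = filter(ledger, .data$component != "facilitator"),
    classroom_only = filter(ledger, .data$stage == 1L)
  )
  rows <- list()
  for (s in c(1L, 2L)) {
    part <- filter(kept, .data$stage == s)
    if (nrow(part) == 0) next
    rows[[length(rows) + 1]] <- tibble(item = part$label, amount_gbp = round(part$amount))
    rows[[length(rows) + 1]] <- tibble(
      item = sprintf("Stage %d subtotal", s),
      amount_gbp = round(if (s == 1L) agg$stage1_subtotal else agg$stage2_subtotal)
    )
  }
  rows[[length(rows) + 1]] <- tibble(
    item = c("Total cost", "Mean cost/school", "Mean cost/pupil"),
    amount_gbp = round(c(agg$total, agg$per_school, agg$per_pupil))
  )
  purrr::list_rbind(rows)
}

#' Render the cost-effectiveness results table
#'
#' Formats the primary incremental estimates (and optional sensitivity
#' rows) in the standard layout: n per arm and "estimate (lo, hi)" strings
#' with two-decimal pounds for costs and two-decimal proportions for
#' effects.
#'
#' @param estimates An `incremental_estimates` object (the primary row).
#' @param sensitivity Optional sensitivity results tibble from
#'   [run_sensitivity()]; omitted from the report when `NULL` or empty.
#' @return A tibble with columns `analysis`, `n_intervention`,
#'   `n_control`, `incremental_cost`, `cases_avoided`.
#' @export
render_table_cea <- function(estimates, sensitivity = NULL) {
  primary <- tibble(
    analysis = "Primary analysis at 33 months",
    n_intervention = estimates$n_intervention,
    n_control = estimates$n_control,
    incremental_cost = fmt_ci(estimates$delta_c, estimates$ci_c[1],
                              estimates$ci_c[2]),
    cases_avoided = fmt_ci(estimates$delta_e, estimates$ci_e[1],
                           estimates$ci_e[2])
  )
  if (is.null(sensitivity) || nrow(sensitivity) == 0) {
    return(primary)
  }
  rows <- sensitivity |>
    mutate(
      analysis = .data$variant,
      incremental_cost = fmt_ci(.data$delta_c, .data$ci_c_lo, .data$ci_c_hi),
      cases_avoided = fmt_ci(.data$delta_e, .data$ci_e_lo, .data$ci_e_hi)
    ) |>
    select("analysis", "n_intervention", "n_control",
           "incremental_cost", "cases_avoided")
  bind_rows(primary, rows)
}
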