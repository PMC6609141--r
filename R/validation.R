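# Simulation-based validation: parameter recovery and bootstrap-CI
# coverage over repeated reduced-scale trials. Used by the package's own
# acceptance checks; exported because calibration studies of this kind are
# something users of a simulation-backed pipeline re-run with their own
# settings.

#' Parameter-recovery and coverage study
#'
#' Repeatedly simulates a trial, runs the full pipeline (costing,
#' complete-case selection, adjusted mixed-model point estimates,
#' school-level bootstrap percentile intervals) and records, per
#' replication, the estimated incremental cost and effect and whether each
#' 95% interval covered the generator's truth.
#'
#' @param n_sims Number of simulated trials.
#' @param config A [trial_config()]; defaults to a reduced-scale trial of
#'   20 schools of ~30 pupils, keeping the study cheap while preserving
#'   the cluster structure.
#' @param B Bootstrap resamples per trial.
#' @param seed Integer seed; trial s uses seed `seed + s` for generation
#'   and the same derived seed for its bootstrap.
#' @param engine Bootstrap replicate engine (see [cluster_bootstrap()]).
#' @return A tibble with one row per replication: `sim`, `delta_c_hat`,
#'   `delta_e_hat`, `cover_c`, `cover_e`, `n_complete`; the generator
#'   truth is attached as attribute `"truth"`.
#' @export
recovery_study <- function(n_sims = 200,
                           config = trial_config(n_schools = 20,
                                                 pupils_per_school = 30),
                           B = 200, seed = 1L, engine = "lm") {
  truth <- NULL
  rows <- purrr::map(seq_len(n_sims), function(s) {
    sim <- simulate_trial(config, seed = seed + s)
    truth <<- sim$truth
    dat <- analysis_dataset(sim)
    cc <- filter(dat, .data$complete)
    est <- cluster_bootstrap(cc, B = B, seed = seed + s, engine = engine)
    covered_c <- est$ci_c[1] <= sim$truth$delta_c &
      sim$truth$delta_c <= est$ci_c[2]
    covered_e <- est$ci_e[1] <= sim$truth$delta_e &
      sim$truth$delta_e <= est$ci_e[2]
    tibble(
      sim = s,
      delta_c_hat = est$delta_c,
      delta_e_hat = est$delta_e,
      cover_c = covered_c,
      cover_e = covered_e,
      n_complete = est$n
    )
  })
  out <- purrr::list_rbind(rows)
  attr(out, "truth") <- truth
  out
}
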