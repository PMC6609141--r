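# Delimited-text interfaces. The file dialects:
#   unit_costs.csv      service_id,label,sector,unit_cost
#   programme_costs.csv stage,component,label,amount
#   service_use.csv     pupil_id,wave,service_id,count  (empty count =
#                       item-missing; a wave with no rows for a pupil is
#                       wave-missing, optionally made explicit by a
#                       pupil_waves.csv flag file pupil_id,wave,wave_missing)

#' Read a unit-cost table from CSV
#'
#' @param path Path to a CSV with columns `service_id`, `label`, `sector`,
#'   `unit_cost`. Defaults to the ledger shipped with the package.
#' @return A validated unit-cost tibble.
#' @export
read_unit_costs <- function(path = system.file("extdata", "unit_costs.csv",
                                               package = "trialcea")) {
  validate_unit_costs(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a programme cost ledger from CSV
#'
#' @param path Path to a CSV with columns `stage`, `component`, `label`,
#'   `amount`. Defaults to the ledger shipped with the package.
#' @param n_schools,n_pupils,n_classes Denominators attached as attributes.
#' @return A programme ledger tibble.
#' @export
read_programme_costs <- function(path = system.file("extdata",
                                                    "programme_costs.csv",
                                                    package = "trialcea"),
                                 n_schools = 105L, n_pupils = 5749L,
                                 n_classes = 192L) {
  tbl <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  assert_columns(tbl, c("stage", "component", "label", "amount"),
                 "programme ledger")
  tbl$stage <- as.integer(tbl$stage)
  attr(tbl, "n_schools") <- n_schools
  attr(tbl, "n_pupils") <- n_pupils
  attr(tbl, "n_classes") <- n_classes
  tbl
}

#' Read long-format service-use records from CSV
#'
#' An empty `count` cell is an item-missing field (costed as zero use); a
#' (pupil, wave) pair with no rows at all is a missing instrument.
#'
#' @param path Path to a CSV with columns `pupil_id`, `wave`,
#'   `service_id`, `count`.
#' @return A tibble ready for [cost_waves()] / [build_cost_dataset()].
#' @export
read_service_use <- function(path) {
  tbl <- as_tibble(utils::read.csv(
    path, stringsAsFactors = FALSE,
    colClasses = c(pupil_id = "character", wave = "character",
                   service_id = "character", count = "integer")
  ))
  assert_columns(tbl, c("pupil_id", "wave", "service_id", "count"),
                 "service_use")
  tbl
}
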