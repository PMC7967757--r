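#' Run the full analysis of one scenario and write its reports
#'
#' Computes the annual flows, the energy report and the economic statement of
#' a scenario and writes them as CSV files plus a JSON summary into a
#' directory. The resolved configuration is written alongside so every run is
#' auditable.
#'
#' @param scenario A `scenario_config`.
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return List with `flows`, `energy` (or `NULL` when the scenario carries
#'   no energy ledger), `statement` and `summary`, invisibly when writing.
#' @export
#' @examples
#' rep <- run_scenario_report(load_concept("III"), out_dir = NULL)
#' rep$summary$roi
run_scenario_report <- function(scenario, out_dir = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  flows <- annualize(scenario$balance, scenario$capacity)
  energy <- if (is.null(scenario$energy_ledger)) NULL
            else energy_report(scenario)
  statement <- economic_statement(scenario)
  summary <- list(
    concept = scenario$concept_id,
    capacity_tRM_per_a = scenario$capacity,
    mass_closure = mass_closure(scenario$balance)$ratio,
    cost_total = statement$cost_total,
    revenue_total = statement$revenue_total,
    profit = statement$profit,
    roi = statement$roi
  )
  if (!is.null(energy)) {
    summary$e_input_mj_per_tRM <- energy$e_input_mj
    summary$e_bm_mj_per_tRM <- energy$e_bm_mj
    summary$energy_ratio <- energy$ratio
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(flows, file.path(out_dir, "flows.csv"), row.names = FALSE)
    if (!is.null(energy))
      utils::write.csv(energy, file.path(out_dir, "energy.csv"),
                       row.names = FALSE)
    write_statement_csv(statement, file.path(out_dir, "statement.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_scenario(scenario, file.path(out_dir, "resolved_config.json"))
    return(invisible(list(flows = flows, energy = energy,
                          statement = statement, summary = summary)))
  }
  list(flows = flows, energy = energy, statement = statement,
       summary = summary)
}

#' Energy report across the four reference concepts
#'
#' Stacks [energy_report()] rows for concepts I-IV (per-concept processing,
#' biogas plant and transport inputs, generated and useful energy), suitable
#' for external plotting.
#'
#' @param file Optional CSV path.
#' @return Data frame with one row per concept.
#' @export
reference_energy_table <- function(file = NULL) {
  ids <- c("I", "II", "III", "IV")
  df <- do.call(rbind, lapply(ids, function(id) energy_report(load_concept(id))))
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Economic statements across the four reference concepts
#'
#' One row per statement line, one column per concept, in million USD per
#' year (unrounded), mirroring the layout of the published cost/revenue
#' tables.
#'
#' @param file Optional CSV path.
#' @return Data frame with columns `section`, `line`, `I`, `II`, `III`, `IV`.
#' @export
reference_statement_table <- function(file = NULL) {
  ids <- c("I", "II", "III", "IV")
  sts <- lapply(ids, function(id) economic_statement(load_concept(id)))
  lines <- function(st) c(st$costs, cost_total = unname(st$cost_total),
                          st$revenues, revenue_total = unname(st$revenue_total),
                          profit = unname(st$profit), roi = unname(st$roi))
  mat <- vapply(sts, lines, lines(sts[[1]]))
  section <- c(rep("cost", length(sts[[1]]$costs) + 1L),
               rep("revenue", length(sts[[1]]$revenues) + 1L),
               "summary", "summary")
  df <- data.frame(section = section, line = rownames(mat),
                   I = mat[, 1] / 1e6, II = mat[, 2] / 1e6,
                   III = mat[, 3] / 1e6, IV = mat[, 4] / 1e6,
                   stringsAsFactors = FALSE, row.names = NULL)
  # ROI stays a fraction, not millions
  roi_row <- df$line == "roi"
  df[roi_row, c("I", "II", "III", "IV")] <-
    df[roi_row, c("I", "II", "III", "IV")] * 1e6
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
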