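#' Build an energy ledger
#'
#' An energy ledger lists the per-operation energy inputs of a scenario: one
#' row per technological operation (grinding, thermal treatment, digester
#' operation, transport, field work, ...) with its direct and indirect energy
#' input in MJ per tonne of raw material. The total input of an operation is
#' direct + indirect, and the system's total energy input is the sum over
#' operations.
#'
#' @param entries Data frame with columns `operation`, `direct`, `indirect`
#'   (MJ/tRM). An optional logical column `reconciliation` marks entries that
#'   close the gap to aggregate figures not attributable to a single printed
#'   operation.
#' @return An `energy_ledger` data frame with a derived `total` column.
#' @export
#' @examples
#' energy_ledger(data.frame(operation = "grinding", direct = 10, indirect = 2))
energy_ledger <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("operation", "direct", "indirect")
  if (!all(need %in% names(entries)))
    stop("ledger needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(entries) == 0L)
    stop("energy ledger is empty", call. = FALSE)
  if (any(!is.finite(entries$direct)) || any(entries$direct < 0) ||
      any(!is.finite(entries$indirect)) || any(entries$indirect < 0))
    stop("direct and indirect energy inputs must be finite and non-negative",
         call. = FALSE)
  if (is.null(entries$reconciliation)) entries$reconciliation <- FALSE
  entries$total <- entries$direct + entries$indirect
  rownames(entries) <- NULL
  class(entries) <- c("energy_ledger", "data.frame")
  entries
}

#' Total energy input of a scenario
#'
#' Sum of direct + indirect energy over all technological operations of the
#' ledger, in MJ per tonne of raw material.
#'
#' @param ledger An `energy_ledger`.
#' @return Total energy input, MJ/tRM.
#' @export
#' @examples
#' total_energy_input(load_concept("I")$energy_ledger)  # 2548
total_energy_input <- function(ledger) {
  stopifnot(inherits(ledger, "energy_ledger"))
  sum(ledger$direct + ledger$indirect)
}

#' Energy balance of a scenario
#'
#' Final useful energy is the energy potential of the biomass minus the total
#' energy input of the system. The input/output ratio (biomass energy over
#' energy input) is reported alongside; it is flagged undefined (`NA`) when
#' the energy input is zero.
#'
#' @param e_bm Energy potential of the biomass (here: biogas CHP heat +
#'   electricity), MJ/tRM. Must be non-negative.
#' @param ledger An `energy_ledger` of the system's energy inputs.
#' @return An `energy_balance_result`: list with `e_bm`, `e_input`, `e_final`
#'   (= `e_bm - e_input`, exactly) and `ratio` (= `e_bm / e_input`, `NA` if
#'   `e_input` is 0).
#' @export
#' @examples
#' cI <- load_concept("I")
#' energy_balance(biomass_energy(cI$biogas), cI$energy_ledger)
energy_balance <- function(e_bm, ledger) {
  if (!is.numeric(e_bm) || length(e_bm) != 1L || is.na(e_bm) || e_bm < 0)
    stop("e_bm must be a single non-negative number", call. = FALSE)
  e_input <- total_energy_input(ledger)
  structure(list(
    e_bm = e_bm,
    e_input = e_input,
    e_final = e_bm - e_input,
    ratio = if (e_input > 0) e_bm / e_input else NA_real_
  ), class = "energy_balance_result")
}

#' @export
print.energy_balance_result <- function(x, ...) {
  cat("<energy_balance_result> (MJ/tRM)\n")
  cat(sprintf("  biomass energy %0.1f - input %0.1f = final %0.1f",
              x$e_bm, x$e_input, x$e_final))
  cat(sprintf("   (output/input ratio %s)\n",
              if (is.na(x$ratio)) "undefined" else sprintf("%.1f", x$ratio)))
  invisible(x)
}

#' Transport energy
#'
#' Energy demand of road transport, linear in mass, distance and the
#' transport energy coefficient.
#'
#' @param mass Transported mass, t.
#' @param distance One-way distance, km.
#' @param coeff Energy coefficient, MJ per t per km (default 0.821: a 24 t
#'   lorry moving one tonne of co-stream 100 km takes 82.1 MJ).
#' @return Energy, MJ.
#' @export
#' @examples
#' transport_energy(1, 100)  # 82.1
transport_energy <- function(mass, distance, coeff = 0.821) {
  vals <- c(mass, distance, coeff)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("mass, distance and coeff must be finite and non-negative",
         call. = FALSE)
  mass * distance * coeff
}

#' Electricity balance
#'
#' Net useful electricity after internal consumption: generation minus the
#' sum over consumers. A negative result means power is purchased from the
#' grid.
#'
#' @param generated Gross electricity generated, kWh/tRM.
#' @param consumers Data frame with columns `name` and `kwh_per_tRM`, or
#'   `NULL`/empty for no internal consumers.
#' @return Net useful electricity, kWh/tRM.
#' @export
#' @examples
#' cI <- load_concept("I")
#' electricity_balance(cI$biogas$electricity_output, cI$electricity_consumers)
electricity_balance <- function(generated, consumers = NULL) {
  if (!is.numeric(generated) || length(generated) != 1L ||
      is.na(generated) || generated < 0)
    stop("generated must be a single non-negative number", call. = FALSE)
  if (is.null(consumers) || NROW(consumers) == 0L) return(generated)
  consumers <- as.data.frame(consumers, stringsAsFactors = FALSE)
  if (!all(c("name", "kwh_per_tRM") %in% names(consumers)))
    stop("consumers needs columns: name, kwh_per_tRM", call. = FALSE)
  if (any(!is.finite(consumers$kwh_per_tRM)) || any(consumers$kwh_per_tRM < 0))
    stop("consumer loads must be finite and non-negative", call. = FALSE)
  generated - sum(consumers$kwh_per_tRM)
}

#' Per-scenario energy report
#'
#' One-row summary of the scenario's energy analysis: processing, biogas
#' plant and transport energy inputs, total input, biomass (CHP) energy,
#' final useful energy and the output/input ratio (MJ/tRM), plus the
#' electricity side (generated, consumed, useful, kWh/tRM).
#'
#' @param scenario A `scenario_config` carrying an `energy_ledger`.
#' @param file Optional CSV path to write the report to.
#' @return A one-row data frame, invisibly when `file` is given.
#' @export
#' @examples
#' energy_report(load_concept("IV"))
energy_report <- function(scenario, file = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(scenario$energy_ledger))
    stop("scenario has no energy ledger", call. = FALSE)
  led <- scenario$energy_ledger
  pick <- function(op) {
    sel <- led$operation == op
    if (any(sel)) sum(led$total[sel]) else 0
  }
  e_bm <- biomass_energy(scenario$biogas)
  bal <- energy_balance(e_bm, led)
  generated <- if (is.null(scenario$biogas)) 0
               else scenario$biogas$electricity_output
  consumed <- if (is.null(scenario$electricity_consumers)) 0
              else sum(scenario$electricity_consumers$kwh_per_tRM)
  useful <- electricity_balance(generated, scenario$electricity_consumers)
  df <- data.frame(
    concept = scenario$concept_id,
    processing_mj = pick("costream_processing"),
    biogas_plant_mj = pick("biogas_plant_operation"),
    transport_mj = pick("transport"),
    other_mj = bal$e_input - pick("costream_processing") -
      pick("biogas_plant_operation") - pick("transport"),
    e_input_mj = bal$e_input,
    e_bm_mj = bal$e_bm,
    e_final_mj = bal$e_final,
    ratio = bal$ratio,
    electricity_generated_kwh = generated,
    electricity_consumed_kwh = consumed,
    electricity_useful_kwh = useful,
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
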