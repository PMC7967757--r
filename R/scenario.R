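#' Assemble a processing scenario
#'
#' Binds one process balance to a plant capacity, the receiving farms, price,
#' investment and operating-cost tables, and (when the concept leaves a
#' residue) a co-digestion biogas/CHP plant. A scenario is the unit on which
#' the energy and economic analyses run.
#'
#' @param concept_id Scenario identifier.
#' @param balance A `process_balance`.
#' @param capacity Plant capacity, t raw material per year (>= 0).
#' @param farm A `farm_spec`.
#' @param prices A `price_table`.
#' @param capex A `capex_spec`.
#' @param opex An `opex_factors`.
#' @param biogas A `biogas_plant_spec`, or `NULL`. Must be present exactly
#'   when the balance has a residue output stream.
#' @param operating_hours Annual operating time, h/a.
#' @param transport_distance Plant-to-farm road distance, km.
#' @param digestate_covers_demand If `TRUE`, digestate replaces the farms'
#'   whole mineral fertiliser demand.
#' @param digestate_offset_t Partial digestate substitution, t/a of
#'   mixed-fertiliser equivalent.
#' @param energy_ledger Optional [energy_ledger()] of per-operation direct and
#'   indirect energy inputs, MJ/tRM.
#' @param electricity_consumers Optional data frame (`name`, `kwh_per_tRM`) of
#'   internal electricity consumers.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(concept_id, balance, capacity, farm, prices,
                            capex, opex, biogas = NULL,
                            operating_hours = 3000,
                            transport_distance = opex$distance,
                            digestate_covers_demand = FALSE,
                            digestate_offset_t = 0,
                            energy_ledger = NULL,
                            electricity_consumers = NULL) {
  obj <- structure(list(
    concept_id = concept_id, balance = balance, capacity = capacity,
    farm = farm, prices = prices, capex = capex, opex = opex,
    biogas = biogas, operating_hours = operating_hours,
    transport_distance = transport_distance,
    digestate_covers_demand = digestate_covers_demand,
    digestate_offset_t = digestate_offset_t,
    energy_ledger = energy_ledger,
    electricity_consumers = electricity_consumers
  ), class = "scenario_config")
  validate_scenario_config(obj)
  obj
}

#' Validate a scenario configuration
#'
#' @param x A `scenario_config`.
#' @return `x`, invisibly, if valid.
#' @export
validate_scenario_config <- function(x) {
  stopifnot(inherits(x$balance, "process_balance"),
            inherits(x$farm, "farm_spec"),
            inherits(x$prices, "price_table"),
            inherits(x$capex, "capex_spec"),
            inherits(x$opex, "opex_factors"))
  if (!is.numeric(x$capacity) || length(x$capacity) != 1L ||
      is.na(x$capacity) || x$capacity < 0)
    stop("capacity must be a single non-negative number", call. = FALSE)
  validate_process_balance(x$balance)
  has_residue <- any(x$balance$streams$name == "residue" &
                     x$balance$streams$role == "output" &
                     x$balance$streams$quantity > 0)
  if (has_residue && is.null(x$biogas))
    stop("balance produces a residue stream but no biogas plant is specified",
         call. = FALSE)
  if (!has_residue && !is.null(x$biogas))
    stop("biogas plant specified but the balance produces no residue stream",
         call. = FALSE)
  if (!is.null(x$biogas)) validate_biogas_plant_spec(x$biogas)
  invisible(x)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> concept %s: %g t_RM/a, %d stream(s), %s\n",
              x$concept_id, x$capacity, nrow(x$balance$streams),
              if (is.null(x$biogas)) "no biogas branch" else "with biogas/CHP"))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

scenario_to_list <- function(x) {
  list(
    concept_id = x$concept_id,
    capacity = x$capacity,
    operating_hours = x$operating_hours,
    transport_distance = x$transport_distance,
    digestate_covers_demand = x$digestate_covers_demand,
    digestate_offset_t = x$digestate_offset_t,
    raw_material = x$balance$raw_material,
    streams = x$balance$streams,
    biogas = if (is.null(x$biogas)) NULL else unclass(x$biogas),
    farm = lapply(unclass(x$farm), function(v)
      if (!is.null(names(v))) as.list(v) else v),
    prices = data.frame(item = x$prices$item, price = x$prices$price,
                        per = x$prices$per),
    capex = unclass(x$capex)[c("processing_investment",
                               "biogas_investment_per_farm",
                               "n_biogas_plants")],
    opex = unclass(x$opex),
    energy_ledger = if (is.null(x$energy_ledger)) NULL
                    else as.data.frame(x$energy_ledger),
    electricity_consumers = x$electricity_consumers
  )
}

# accept data frames, column-lists (yaml) and lists of row-maps
rows_to_df <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x) && length(x) && all(!nzchar(names(x) %||% ""))) {
    return(do.call(rbind, lapply(x, function(r)
      as.data.frame(r, stringsAsFactors = FALSE))))
  }
  as.data.frame(x, stringsAsFactors = FALSE)
}

scenario_from_list <- function(l) {
  farm_args <- l$farm
  farm_args$nutrient_requirement <- unlist(farm_args$nutrient_requirement)
  biogas <- if (is.null(l$biogas)) NULL else {
    b <- l$biogas
    biogas_plant_spec(
      residue_input = b$residue_input, manure_input = b$manure_input,
      biogas_yield = b$biogas_yield, methane_fraction = b$methane_fraction,
      heat_output = b$heat_output, electricity_output = b$electricity_output,
      fertiliser_output = b$fertiliser_output %||% 0,
      digester_volume = b$digester_volume %||% 2300,
      organic_loading_rate = b$organic_loading_rate %||% 2,
      ts_input = b$ts_input %||% 0.121,
      self_consumption_energy = b$self_consumption_energy %||% 0,
      self_consumption_electricity = b$self_consumption_electricity %||% 0)
  }
  streams <- rows_to_df(l$streams)
  prices <- rows_to_df(l$prices)
  ledger <- if (is.null(l$energy_ledger)) NULL else
    energy_ledger(rows_to_df(l$energy_ledger))
  consumers <- rows_to_df(l$electricity_consumers)
  scenario_config(
    concept_id = l$concept_id,
    balance = process_balance(l$concept_id, streams,
                              raw_material = l$raw_material %||% "fish_costream"),
    capacity = l$capacity,
    farm = do.call(farm_spec, farm_args),
    prices = price_table(prices$item, prices$price, prices$per),
    capex = do.call(capex_spec, l$capex),
    opex = do.call(opex_factors, l$opex),
    biogas = biogas,
    operating_hours = l$operating_hours %||% 3000,
    transport_distance = l$transport_distance %||% 100,
    digestate_covers_demand = isTRUE(l$digestate_covers_demand),
    digestate_offset_t = l$digestate_offset_t %||% 0,
    energy_ledger = ledger,
    electricity_consumers = consumers
  )
}

#' Read and write scenario configurations
#'
#' Scenarios are stored as structured configuration files, JSON or YAML
#' (chosen from the file extension). A written scenario reloads to identical
#' annual flows.
#'
#' @param x A `scenario_config`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a validated `scenario_config`.
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "scenario_config"))
  l <- scenario_to_list(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    l <- rapply(l, function(d) d, classes = "data.frame", how = "replace",
                deflt = NULL)
    l$streams <- as.list(as.data.frame(l$streams))
    l$prices <- as.list(as.data.frame(l$prices))
    if (!is.null(l$energy_ledger))
      l$energy_ledger <- as.list(as.data.frame(l$energy_ledger))
    if (!is.null(l$electricity_consumers))
      l$electricity_consumers <- as.list(as.data.frame(l$electricity_consumers))
    yaml::write_yaml(l, path, precision = 15)
  } else stop("unsupported scenario format: .", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  l <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported scenario format: .", ext, call. = FALSE)
  scenario_from_list(l)
}

#' Export annual flows as CSV
#'
#' @param scenario A `scenario_config`.
#' @param file CSV path, or `NULL` to skip writing.
#' @return Data frame with columns `stream`, `role`, `unit`, `per_tRM`,
#'   `annual`, invisibly.
#' @export
write_flows_csv <- function(scenario, file = NULL) {
  df <- annualize(scenario$balance, scenario$capacity)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
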