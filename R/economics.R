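#' Create a price table
#'
#' Market prices for every stream a scenario buys or sells. Each entry has a
#' unit basis (`per`): `"t"`, `"kg"`, `"MWh"` or `"m3"`; the costing engine
#' converts annual flows (t/a, kWh/a, m3/a) to that basis.
#'
#' @param items Character vector of stream/utility identifiers.
#' @param prices Numeric vector of unit prices in USD (all > 0).
#' @param per Character vector of unit bases, same length.
#' @return A `price_table` data frame with columns `item`, `price`, `per`.
#' @export
#' @examples
#' default_prices()
price_table <- function(items, prices, per) {
  stopifnot(length(items) == length(prices), length(items) == length(per))
  if (any(!is.finite(prices)) || any(prices <= 0))
    stop("all prices must be positive", call. = FALSE)
  if (anyDuplicated(items))
    stop("duplicate price items", call. = FALSE)
  bad <- setdiff(unique(per), c("t", "kg", "MWh", "m3"))
  if (length(bad))
    stop("unknown price basis: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(item = as.character(items), price = as.numeric(prices),
                    per = as.character(per), stringsAsFactors = FALSE)
  class(out) <- c("price_table", class(out))
  out
}

#' Reference market prices
#'
#' The price set used by the four reference concepts: fish co-stream and
#' auxiliary chemicals on the buy side, oil/protein/meal products, silage and
#' electricity on the sell side, plus mineral fertilisers for the farms.
#'
#' @return A `price_table`.
#' @export
default_prices <- function() {
  price_table(
    items = c("fish_costream", "formic_acid", "enzyme", "steam",
              "electricity", "water", "premium_oil", "oil",
              "fish_protein_hydrolysate", "fish_protein_concentrate",
              "meal", "silage", "mineral_fertilisers"),
    prices = c(120, 1000, 20, 20, 100, 0.1, 1350, 1200, 3900, 900,
               1350, 240, 500),
    per = c("t", "t", "kg", "t", "MWh", "m3", "t", "t", "t", "t",
            "t", "t", "t")
  )
}

# price of one item; named error when absent
price_of <- function(prices, item) {
  i <- match(item, prices$item)
  if (is.na(i))
    stop("no price entry for stream '", item, "'", call. = FALSE)
  prices[i, c("price", "per")]
}

# USD value of an annual flow priced per its table basis
flow_value <- function(annual, flow_unit, price, per) {
  conv <- switch(paste(flow_unit, per),
    "t/a t"     = 1,
    "t/a kg"    = 1000,
    "kWh/a MWh" = 1e-3,
    "kWh/a kWh" = 1,
    "m3/a m3"   = 1,
    stop("cannot price a flow in ", flow_unit, " with a price per ", per,
         call. = FALSE))
  annual * conv * price
}

#' Capital investment specification
#'
#' @param processing_investment Investment in the co-stream processing plant,
#'   USD (0 when the whole co-stream goes straight to digestion).
#' @param biogas_investment_per_farm Investment per farm-scale biogas plant, USD.
#' @param n_biogas_plants Number of biogas plants built.
#' @return A `capex_spec` with the derived `total_investment`.
#' @export
capex_spec <- function(processing_investment = 0,
                       biogas_investment_per_farm = 0,
                       n_biogas_plants = 0) {
  vals <- c(processing_investment, biogas_investment_per_farm, n_biogas_plants)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("investment figures must be finite and non-negative", call. = FALSE)
  structure(list(
    processing_investment = processing_investment,
    biogas_investment_per_farm = biogas_investment_per_farm,
    n_biogas_plants = n_biogas_plants,
    total_investment = processing_investment +
      n_biogas_plants * biogas_investment_per_farm
  ), class = "capex_spec")
}

#' Operating cost factors
#'
#' @param operators Number of plant operators.
#' @param salary Annual salary per operator, USD/a.
#' @param indirect_labour_frac Indirect labour costs as a fraction of salary.
#' @param maintenance_frac Annual maintenance as a fraction of total investment.
#' @param depreciation_time Straight-line depreciation period, years.
#' @param other_indirect_frac Other indirect costs as a fraction of investment.
#' @param logistics_rate Road transport cost, USD per t per km.
#' @param distance Transport distance plant -> farm, km.
#' @return An `opex_factors` object.
#' @export
opex_factors <- function(operators,
                         salary = 65000,
                         indirect_labour_frac = 0.40,
                         maintenance_frac = 0.025,
                         depreciation_time = 15,
                         other_indirect_frac = 0.01,
                         logistics_rate = 0.1,
                         distance = 100) {
  fr <- c(indirect_labour_frac, maintenance_frac, other_indirect_frac)
  if (any(fr < 0) || any(fr > 1))
    stop("cost fractions must lie in [0, 1]", call. = FALSE)
  if (!is.finite(depreciation_time) || depreciation_time <= 0)
    stop("depreciation_time must be positive", call. = FALSE)
  vals <- c(operators, salary, logistics_rate, distance)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("operating cost factors must be finite and non-negative", call. = FALSE)
  structure(list(operators = operators, salary = salary,
                 indirect_labour_frac = indirect_labour_frac,
                 maintenance_frac = maintenance_frac,
                 depreciation_time = depreciation_time,
                 other_indirect_frac = other_indirect_frac,
                 logistics_rate = logistics_rate, distance = distance),
            class = "opex_factors")
}

# streams treated as purchased utilities rather than raw materials
utility_streams <- function() c("steam", "electricity", "water")

# streams that never cross the battery limit (internal transfers)
internal_streams <- function() c("residue", "fertilisers", "digestate")

# revenue grouping of the reference products; anything else sells as "other"
revenue_group <- function(name) {
  groups <- c(premium_oil = "oil", oil = "oil",
              fish_protein_hydrolysate = "protein",
              fish_protein_concentrate = "protein",
              meal = "meal", silage = "meal")
  ifelse(name %in% names(groups), groups[name], "other")
}

#' Farm mineral fertiliser balance
#'
#' Annual mixed mineral fertiliser demand of the farms and its cost. Demand is
#' `n_farms * (manured_area * rate_manured + mineral_only_area *
#' rate_mineral_only)`. When the digestate from co-digestion covers the whole
#' requirement the demand is zero; a partial digestate nutrient offset (in
#' tonnes of mixed-fertiliser equivalent) reduces it.
#'
#' @param farm A `farm_spec`.
#' @param prices A `price_table` with a `mineral_fertilisers` entry.
#' @param digestate_covers_demand If `TRUE`, digestate replaces all mineral
#'   fertiliser (demand 0).
#' @param digestate_offset_t Mixed-fertiliser-equivalent tonnes substituted by
#'   digestate per year (clamped so residual demand is never negative).
#' @return A list with `demand_t` (t/a) and `cost` (USD/a).
#' @export
#' @examples
#' fertiliser_balance(farm_spec(), default_prices())  # 1201.6 t -> 600,800 USD
fertiliser_balance <- function(farm, prices,
                               digestate_covers_demand = FALSE,
                               digestate_offset_t = 0) {
  stopifnot(inherits(farm, "farm_spec"))
  if (digestate_covers_demand)
    return(list(demand_t = 0, cost = 0))
  demand_kg <- farm$n_farms *
    (farm$manured_area * farm$mixed_fertiliser_rate_manured +
     farm$mineral_only_area * farm$mixed_fertiliser_rate_mineral_only)
  demand_t <- demand_kg / 1000 - digestate_offset_t
  if (demand_t < 0) {
    warning("digestate offset exceeds fertiliser demand; clamping to 0",
            call. = FALSE)
    demand_t <- 0
  }
  p <- price_of(prices, "mineral_fertilisers")
  list(demand_t = demand_t,
       cost = flow_value(demand_t, "t/a", p$price, p$per))
}

#' Annual cost statement
#'
#' Builds the cost side of the annual economic statement: purchased raw
#' materials and utilities priced from the annual flows, labour, residue
#' logistics, maintenance and other indirect costs as fractions of the
#' investment, straight-line depreciation, and the farm mineral fertiliser
#' bill.
#'
#' @param scenario A `scenario_config`.
#' @param prices,capex,opex Optional overrides of the scenario's own tables.
#' @return Named numeric vector of cost lines (USD/a) with a `total` attribute
#'   accessible via `sum()`; lines: `raw_materials`, `utilities`, `labour`,
#'   `logistics`, `maintenance`, `depreciation`, `other_indirect`,
#'   `mineral_fertilisers`.
#' @export
cost_statement <- function(scenario, prices = scenario$prices,
                           capex = scenario$capex, opex = scenario$opex) {
  flows <- annualize(scenario$balance, scenario$capacity)
  ins <- flows[flows$role == "input" & !(flows$stream %in% internal_streams()), ]
  is_util <- ins$stream %in% utility_streams()
  line_value <- function(rows) {
    if (nrow(rows) == 0L) return(0)
    total <- 0
    for (i in seq_len(nrow(rows))) {
      p <- price_of(prices, rows$stream[i])
      total <- total + flow_value(rows$annual[i], rows$unit[i], p$price, p$per)
    }
    total
  }
  residue_t <- flows$annual[flows$role == "output" & flows$stream == "residue" &
                            flows$unit == "t/a"]
  residue_t <- if (length(residue_t)) sum(residue_t) else 0
  fert <- fertiliser_balance(
    scenario$farm, prices,
    digestate_covers_demand = isTRUE(scenario$digestate_covers_demand),
    digestate_offset_t = scenario$digestate_offset_t %||% 0
  )
  c(raw_materials = line_value(ins[!is_util, ]),
    utilities = line_value(ins[is_util, ]),
    labour = opex$operators * opex$salary * (1 + opex$indirect_labour_frac),
    logistics = residue_t * opex$distance * opex$logistics_rate,
    maintenance = opex$maintenance_frac * capex$total_investment,
    depreciation = capex$total_investment / opex$depreciation_time,
    other_indirect = opex$other_indirect_frac * capex$total_investment,
    mineral_fertilisers = fert$cost)
}

#' Annual revenue statement
#'
#' Prices every sold product from the annual flows and groups the lines as
#' `oil` (premium oil + oil), `protein` (hydrolysate or concentrate), `meal`
#' (meal or silage), `other` (any non-reference product), and `energy`
#' (gross CHP electricity sold at the electricity price; heat is used
#' internally and not sold).
#'
#' @inheritParams cost_statement
#' @return Named numeric vector of revenue lines (USD/a):
#'   `oil`, `protein`, `meal`, `other`, `energy`.
#' @export
revenue_statement <- function(scenario, prices = scenario$prices) {
  flows <- annualize(scenario$balance, scenario$capacity)
  outs <- flows[flows$role == "output" &
                !(flows$stream %in% internal_streams()), ]
  lines <- c(oil = 0, protein = 0, meal = 0, other = 0, energy = 0)
  if (nrow(outs)) {
    grp <- revenue_group(outs$stream)
    for (i in seq_len(nrow(outs))) {
      p <- price_of(prices, outs$stream[i])
      lines[grp[i]] <- lines[grp[i]] +
        flow_value(outs$annual[i], outs$unit[i], p$price, p$per)
    }
  }
  if (!is.null(scenario$biogas)) {
    p <- price_of(prices, "electricity")
    gross_kwh <- scenario$biogas$electricity_output * scenario$capacity
    lines["energy"] <- flow_value(gross_kwh, "kWh/a", p$price, p$per)
  }
  lines
}

#' Full annual economic statement
#'
#' Combines [cost_statement()] and [revenue_statement()] into one statement
#' with totals, annual net profit and return on investment. All arithmetic is
#' unrounded; [format()] and [print()] round to the reporting precision
#' (0.1 million USD, whole percent).
#'
#' @inheritParams cost_statement
#' @return An `economic_statement`: list with `costs`, `revenues`,
#'   `cost_total`, `revenue_total`, `profit`, `roi`, `concept_id`,
#'   `total_investment`.
#' @export
#' @examples
#' economic_statement(load_concept("I"))
economic_statement <- function(scenario, prices = scenario$prices,
                               capex = scenario$capex, opex = scenario$opex) {
  costs <- cost_statement(scenario, prices, capex, opex)
  revenues <- revenue_statement(scenario, prices)
  pr <- profit_and_roi_values(sum(revenues) - sum(costs), capex)
  structure(list(concept_id = scenario$concept_id,
                 costs = costs, revenues = revenues,
                 cost_total = sum(costs), revenue_total = sum(revenues),
                 profit = pr$profit, roi = pr$roi,
                 total_investment = capex$total_investment),
            class = "economic_statement")
}

profit_and_roi_values <- function(profit, capex) {
  roi <- if (capex$total_investment > 0) profit / capex$total_investment
         else NA_real_
  list(profit = profit, roi = roi)
}

#' Profit and return on investment
#'
#' Annual net profit (revenue total minus cost total, computed on unrounded
#' line values) and ROI = profit / total investment.
#'
#' @param statement An `economic_statement`.
#' @param capex Optional `capex_spec` override; defaults to the investment
#'   recorded in the statement.
#' @return List with `profit` (USD/a) and `roi` (fraction; `NA` when the
#'   investment is zero).
#' @export
profit_and_roi <- function(statement, capex = NULL) {
  stopifnot(inherits(statement, "economic_statement"))
  total_inv <- if (is.null(capex)) statement$total_investment
               else capex$total_investment
  profit <- statement$revenue_total - statement$cost_total
  list(profit = profit,
       roi = if (total_inv > 0) profit / total_inv else NA_real_)
}

#' @export
print.economic_statement <- function(x, ...) {
  m <- function(v) sprintf("%6.1f", v / 1e6)
  cat("<economic_statement> concept", x$concept_id, "(million USD per year)\n")
  cat("costs:\n")
  for (nm in names(x$costs)) cat(sprintf("  %-20s %s\n", nm, m(x$costs[nm])))
  cat(sprintf("  %-20s %s\n", "total", m(x$cost_total)))
  cat("revenues:\n")
  for (nm in names(x$revenues))
    if (x$revenues[nm] != 0) cat(sprintf("  %-20s %s\n", nm, m(x$revenues[nm])))
  cat(sprintf("  %-20s %s\n", "total", m(x$revenue_total)))
  cat(sprintf("profit: %s  ROI: %s%%\n", m(x$profit),
              if (is.na(x$roi)) "NA" else round(100 * x$roi)))
  invisible(x)
}

#' Export an economic statement
#'
#' Writes the statement as a line-item CSV (columns `section`, `line`,
#' `usd_per_a`) and returns the data frame invisibly. A JSON summary
#' (`concept`, `profit`, `roi`, totals) can be written alongside.
#'
#' @param statement An `economic_statement`.
#' @param file Path of the CSV to write, or `NULL` to skip writing.
#' @param json_file Optional path of a JSON summary.
#' @return The line-item data frame, invisibly.
#' @export
write_statement_csv <- function(statement, file = NULL, json_file = NULL) {
  df <- rbind(
    data.frame(section = "cost", line = names(statement$costs),
               usd_per_a = unname(statement$costs)),
    data.frame(section = "revenue", line = names(statement$revenues),
               usd_per_a = unname(statement$revenues)),
    data.frame(section = "summary",
               line = c("cost_total", "revenue_total", "profit"),
               usd_per_a = c(statement$cost_total, statement$revenue_total,
                             statement$profit))
  )
  if (!is.null(file))
    utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(
      list(concept = statement$concept_id, profit = statement$profit,
           roi = statement$roi, cost_total = statement$cost_total,
           revenue_total = statement$revenue_total),
      json_file, auto_unbox = TRUE, digits = NA)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
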