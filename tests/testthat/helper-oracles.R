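# Independent brute-force oracles: spreadsheet-style recomputations written
# against the raw stream tables, deliberately not reusing the package's
# costing or annualisation internals.

utility_set <- c("steam", "electricity", "water")
internal_set <- c("residue", "fertilisers", "digestate")

# annual quantity of one coefficient in its pricing basis (t, kWh or m3)
oracle_annual <- function(qty, unit, capacity) {
  switch(unit,
    "kg/tRM" = qty * capacity / 1000,
    "t/tRM" = qty * capacity,
    "kWh/tRM" = qty * capacity,
    "m3/tRM" = qty * capacity,
    stop("oracle: unknown unit ", unit))
}

# USD value of one priced annual amount
oracle_value <- function(amount, unit, price, per) {
  if (unit %in% c("kg/tRM", "t/tRM") && per == "t") return(amount * price)
  if (unit %in% c("kg/tRM", "t/tRM") && per == "kg") return(amount * 1000 * price)
  if (unit == "kWh/tRM" && per == "MWh") return(amount / 1000 * price)
  if (unit == "kWh/tRM" && per == "kWh") return(amount * price)
  if (unit == "m3/tRM" && per == "m3") return(amount * price)
  stop("oracle: cannot price ", unit, " per ", per)
}

# full statement by explicit loops over streams x prices
oracle_statement <- function(scen, prices = scen$prices) {
  s <- scen$balance$streams
  cap <- scen$capacity
  p_of <- function(nm) prices[match(nm, prices$item), ]
  raw <- 0; util <- 0; rev <- 0
  for (i in seq_len(nrow(s))) {
    pr <- p_of(s$name[i])
    amt <- oracle_annual(s$quantity[i], s$unit[i], cap)
    if (s$role[i] == "input") {
      v <- oracle_value(amt, s$unit[i], pr$price, pr$per)
      if (s$name[i] %in% utility_set) util <- util + v else raw <- raw + v
    } else if (!(s$name[i] %in% internal_set)) {
      rev <- rev + oracle_value(amt, s$unit[i], pr$price, pr$per)
    }
  }
  if (!is.null(scen$biogas)) {
    pe <- p_of("electricity")
    rev <- rev + oracle_value(scen$biogas$electricity_output * cap,
                              "kWh/tRM", pe$price, pe$per)
  }
  residue_t <- 0
  for (i in seq_len(nrow(s)))
    if (s$role[i] == "output" && s$name[i] == "residue")
      residue_t <- residue_t + oracle_annual(s$quantity[i], s$unit[i], cap)
  labour <- scen$opex$operators * scen$opex$salary *
    (1 + scen$opex$indirect_labour_frac)
  logistics <- residue_t * scen$opex$distance * scen$opex$logistics_rate
  inv <- scen$capex$processing_investment +
    scen$capex$n_biogas_plants * scen$capex$biogas_investment_per_farm
  maintenance <- scen$opex$maintenance_frac * inv
  depreciation <- inv / scen$opex$depreciation_time
  other <- scen$opex$other_indirect_frac * inv
  fert_cost <- if (isTRUE(scen$digestate_covers_demand)) 0 else {
    f <- scen$farm
    demand <- f$n_farms * (f$manured_area * f$mixed_fertiliser_rate_manured +
      f$mineral_only_area * f$mixed_fertiliser_rate_mineral_only) / 1000
    demand <- max(demand - (scen$digestate_offset_t %||% 0), 0)
    demand * p_of("mineral_fertilisers")$price
  }
  cost <- raw + util + labour + logistics + maintenance + depreciation +
    other + fert_cost
  list(cost_total = cost, revenue_total = rev, profit = rev - cost)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic one-at-a-time swing of one factor: 2v times the absolute net
# exposure (sold minus bought value of the factor's items at base prices)
oracle_swing <- function(scen, cfg, f) {
  items <- cfg$factor_map[[f]]
  items <- c(items, names(cfg$correlation_groups)[cfg$correlation_groups == f])
  s <- scen$balance$streams
  prices <- scen$prices
  net <- 0
  for (i in seq_len(nrow(s))) {
    if (!(s$name[i] %in% items) || s$name[i] %in% internal_set) next
    pr <- prices[match(s$name[i], prices$item), ]
    amt <- oracle_annual(s$quantity[i], s$unit[i], scen$capacity)
    v <- oracle_value(amt, s$unit[i], pr$price, pr$per)
    net <- net + if (s$role[i] == "output") v else -v
  }
  if (!is.null(scen$biogas) && "electricity" %in% items) {
    pe <- prices[match("electricity", prices$item), ]
    net <- net + oracle_value(scen$biogas$electricity_output * scen$capacity,
                              "kWh/tRM", pe$price, pe$per)
  }
  if ("mineral_fertilisers" %in% items &&
      !isTRUE(scen$digestate_covers_demand)) {
    f2 <- scen$farm
    demand <- f2$n_farms *
      (f2$manured_area * f2$mixed_fertiliser_rate_manured +
       f2$mineral_only_area * f2$mixed_fertiliser_rate_mineral_only) / 1000
    demand <- max(demand - (scen$digestate_offset_t %||% 0), 0)
    net <- net - demand * prices$price[prices$item == "mineral_fertilisers"]
  }
  2 * cfg$variation * abs(net)
}
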