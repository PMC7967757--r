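# local RNG scope: seed the stream, restore the caller's state on exit
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a synthetic scenario
#'
#' Parameters of the random scenario generator used for property testing.
#' Generated scenarios have the same structural shape as the reference
#' concepts — a 1000 kg/tRM raw-material input, a random product slate,
#' utility draws, optionally a residue stream feeding a co-digestion branch —
#' and satisfy all structural validators by construction.
#'
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @param n_products Number of saleable products (>= 1).
#' @param coefficient_range Range the raw product-yield draws are taken from
#'   (kg/tRM) before rescaling to the target mass closure.
#' @param closure_range Range of the target mass closure (fraction of the
#'   raw-material mass leaving as kg-denominated outputs), within (0, 1].
#' @param price_range Range of product prices, USD/t.
#' @param capex_range Range of the processing investment, USD.
#' @param has_residue If `TRUE` the scenario leaves a residue stream and gets
#'   a biogas/CHP branch.
#' @return A `synthetic_scenario_spec` object.
#' @export
synthetic_scenario_spec <- function(seed,
                                    n_products = 3,
                                    coefficient_range = c(50, 300),
                                    closure_range = c(0.3, 0.95),
                                    price_range = c(100, 4000),
                                    capex_range = c(1e6, 12e6),
                                    has_residue = TRUE) {
  ranges <- list(coefficient_range = coefficient_range,
                 closure_range = closure_range,
                 price_range = price_range, capex_range = capex_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("infeasible ", nm, ": min exceeds max", call. = FALSE)
  }
  if (any(coefficient_range < 0) || any(price_range <= 0) ||
      any(capex_range < 0))
    stop("coefficient, price and capex ranges must be non-negative", call. = FALSE)
  if (closure_range[1] <= 0 || closure_range[2] > 1)
    stop("closure_range must lie within (0, 1]", call. = FALSE)
  if (!is.numeric(n_products) || n_products < 1)
    stop("n_products must be at least 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_products = as.integer(n_products),
                 coefficient_range = coefficient_range,
                 closure_range = closure_range,
                 price_range = price_range, capex_range = capex_range,
                 has_residue = isTRUE(has_residue)),
            class = "synthetic_scenario_spec")
}

#' Generate a random synthetic scenario
#'
#' Draws a reproducible random [scenario_config()] from a
#' [synthetic_scenario_spec()]. Mass closure holds by construction: product
#' and residue yields are rescaled so kg-denominated outputs never exceed the
#' raw-material input. When a residue is generated, the biogas branch's CHP
#' output is drawn below the chemical energy of the methane produced, so the
#' plant validator holds for every seed. The caller's RNG state is left
#' untouched.
#'
#' @param spec A `synthetic_scenario_spec`.
#' @return A validated `scenario_config`.
#' @export
#' @examples
#' s <- generate_scenario(synthetic_scenario_spec(seed = 42))
#' mass_closure(s$balance)$ratio
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "synthetic_scenario_spec"))
  with_seed(spec$seed, {
    closure <- stats::runif(1, spec$closure_range[1], spec$closure_range[2])
    residue_q <- if (spec$has_residue)
      stats::runif(1, 0.1, 0.4) * 1000 * closure else 0
    raw_yields <- stats::runif(spec$n_products, spec$coefficient_range[1],
                               spec$coefficient_range[2])
    product_mass <- 1000 * closure - residue_q
    yields <- raw_yields / sum(raw_yields) * product_mass
    products <- paste0("product_", seq_len(spec$n_products))

    streams <- rbind(
      data.frame(name = "fish_costream", role = "input", quantity = 1000,
                 unit = "kg/tRM"),
      data.frame(name = "aux_chemical", role = "input",
                 quantity = stats::runif(1, 0, 10), unit = "kg/tRM"),
      data.frame(name = "steam", role = "input",
                 quantity = stats::runif(1, 0, 2), unit = "t/tRM"),
      data.frame(name = "electricity", role = "input",
                 quantity = stats::runif(1, 10, 80), unit = "kWh/tRM"),
      data.frame(name = products, role = "output", quantity = yields,
                 unit = "kg/tRM")
    )
    if (spec$has_residue)
      streams <- rbind(streams,
        data.frame(name = "residue", role = "output", quantity = residue_q,
                   unit = "kg/tRM"))

    biogas <- NULL
    if (spec$has_residue && residue_q > 0) {
      residue_in <- residue_q / 1000
      yield <- stats::runif(1, 60, 110)
      ch4 <- stats::runif(1, 0.55, 0.70)
      feed <- 6 * residue_in
      methane_mj <- feed * yield * ch4 * CH4_LHV_MJ_M3
      chp_eff <- stats::runif(1, 0.5, 0.85)
      elec_share <- stats::runif(1, 0.3, 0.5)
      chp_kwh <- methane_mj * chp_eff / KWH_TO_MJ
      biogas <- biogas_plant_spec(
        residue_input = residue_in, manure_input = 5 * residue_in,
        biogas_yield = yield, methane_fraction = ch4,
        heat_output = chp_kwh * (1 - elec_share),
        electricity_output = chp_kwh * elec_share,
        fertiliser_output = feed * stats::runif(1, 700, 950),
        self_consumption_energy = methane_mj * stats::runif(1, 0.1, 0.3),
        self_consumption_electricity = chp_kwh * stats::runif(1, 0.05, 0.2))
    }

    prices <- price_table(
      items = c("fish_costream", "aux_chemical", "steam", "electricity",
                "water", "mineral_fertilisers", products),
      prices = c(stats::runif(1, 80, 160), stats::runif(1, 500, 1500),
                 stats::runif(1, 10, 30), stats::runif(1, 50, 150),
                 0.1, stats::runif(1, 300, 700),
                 stats::runif(spec$n_products, spec$price_range[1],
                              spec$price_range[2])),
      per = c("t", "t", "t", "MWh", "m3", "t", rep("t", spec$n_products))
    )

    capex <- capex_spec(
      processing_investment = stats::runif(1, spec$capex_range[1],
                                           spec$capex_range[2]),
      biogas_investment_per_farm = if (is.null(biogas)) 0
                                   else stats::runif(1, 1e6, 3e6),
      n_biogas_plants = if (is.null(biogas)) 0 else sample(1:4, 1))

    ledger <- energy_ledger(data.frame(
      operation = c("costream_processing", "transport",
                    if (!is.null(biogas)) "biogas_plant_operation"),
      direct = stats::runif(if (is.null(biogas)) 2 else 3, 0, 500),
      indirect = stats::runif(if (is.null(biogas)) 2 else 3, 0, 100)))

    scenario_config(
      concept_id = paste0("synthetic_", spec$seed),
      balance = process_balance(paste0("synthetic_", spec$seed), streams),
      capacity = round(stats::runif(1, 1000, 20000)),
      farm = farm_spec(),
      prices = prices,
      capex = capex,
      opex = opex_factors(operators = sample(1:6, 1)),
      biogas = biogas,
      digestate_covers_demand = FALSE,
      digestate_offset_t = if (is.null(biogas)) 0 else stats::runif(1, 0, 300),
      energy_ledger = ledger,
      electricity_consumers = data.frame(
        name = "costream_processing",
        kwh_per_tRM = streams$quantity[streams$name == "electricity"])
    )
  })
}
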