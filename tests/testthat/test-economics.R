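test_that("cost lines price the annual flows and the fixed factors", {
  cI <- load_concept("I")
  costs <- cost_statement(cI)
  expect_equal(unname(costs["raw_materials"]), 1.2e6)   # 10,000 t x 120 USD/t
  expect_equal(unname(costs["depreciation"]), 10.4e6 / 15)
  expect_equal(unname(costs["utilities"]), 0)           # no purchased utilities
  expect_equal(unname(costs["logistics"]), 0.1e6)       # 10,000 t x 100 km x 0.1
  expect_equal(unname(costs["mineral_fertilisers"]), 0) # digestate covers demand

  # missing price for a purchased stream is a named error
  pruned <- cI$prices[cI$prices$item != "fish_costream", ]
  class(pruned) <- class(cI$prices)
  expect_error(cost_statement(cI, prices = pruned), "fish_costream")
})

test_that("a zero-capacity scenario keeps only the fixed cost lines", {
  cI <- load_concept("I")
  zero <- scenario_config("I0", cI$balance, 0, cI$farm, cI$prices, cI$capex,
                          cI$opex, biogas = cI$biogas,
                          digestate_covers_demand = TRUE)
  costs <- cost_statement(zero)
  expect_equal(unname(costs[c("raw_materials", "utilities", "logistics",
                              "mineral_fertilisers")]), rep(0, 4))
  expect_true(all(costs[c("labour", "maintenance", "depreciation",
                          "other_indirect")] > 0))
})

test_that("revenue lines group the product slate and gross CHP power", {
  expect_equal(unname(revenue_statement(load_concept("II"))["meal"]), 2.4e6)
  revIV <- revenue_statement(load_concept("IV"))
  expect_equal(unname(revIV["oil"]), (175 * 1350 + 46 * 1200) * 10)  # 2.9145e6
  expect_equal(unname(revIV["protein"]), 1710 * 3900)
  expect_equal(unname(revIV["energy"]), 158 * 10000 / 1000 * 100)    # gross CHP
  # residue is an internal transfer, never sold
  expect_false("residue" %in% names(revIV))

  # empty product slate: all revenue lines zero
  bare <- load_concept("II")
  bal <- process_balance("bare", data.frame(
    name = "fish_costream", role = "input", quantity = 1000, unit = "kg/tRM"))
  empty <- scenario_config("bare", bal, 10000, bare$farm, bare$prices,
                           bare$capex, bare$opex)
  expect_true(all(revenue_statement(empty) == 0))
})

test_that("the farm fertiliser balance follows the split application rates", {
  farm <- farm_spec()
  prices <- default_prices()
  fb <- fertiliser_balance(farm, prices)
  expect_equal(fb$demand_t, 4 * (400 * 484 + 200 * 534) / 1000)  # 1201.6 t
  expect_equal(fb$cost, 0.6008e6)
  expect_equal(fertiliser_balance(farm, prices,
                                  digestate_covers_demand = TRUE)$cost, 0)
  expect_equal(fertiliser_balance(farm, prices,
                                  digestate_offset_t = 201.6)$cost, 0.5e6)
  # over-offset clamps at zero with a warning
  expect_warning(
    fb0 <- fertiliser_balance(farm, prices, digestate_offset_t = 5000),
    "clamping")
  expect_equal(fb0$cost, 0)
  # zero area, zero demand
  zero_farm <- farm_spec(area_per_farm = 0, manured_area = 0,
                         mineral_only_area = 0)
  expect_equal(fertiliser_balance(zero_farm, prices)$cost, 0)
})

test_that("profit and ROI derive from unrounded totals", {
  stI <- economic_statement(load_concept("I"))
  pr <- profit_and_roi(stI)
  expect_equal(pr$profit, stI$revenue_total - stI$cost_total)
  expect_equal(round(pr$profit / 1e6, 1), -1.3)
  expect_equal(round(100 * pr$roi), -13)
  expect_equal(round(100 * economic_statement(load_concept("III"))$roi), 42)

  # zero profit gives ROI 0; zero investment flags ROI undefined
  fake <- stI
  fake$revenue_total <- fake$cost_total
  expect_equal(profit_and_roi(fake)$roi, 0)
  expect_true(is.na(profit_and_roi(stI, capex = capex_spec(0, 0, 0))$roi))
})

test_that("statement identity and oracle equivalence hold on random scenarios", {
  for (seed in 1:30) {
    scen <- generate_scenario(
      synthetic_scenario_spec(seed = seed, has_residue = seed %% 2 == 0))
    st <- economic_statement(scen)
    # identity: profit + costs = revenues, exactly
    expect_equal(st$profit + st$cost_total, st$revenue_total)
    expect_equal(st$cost_total, sum(st$costs))
    expect_equal(st$revenue_total, sum(st$revenues))
    # equivalence with the explicit loop recomputation
    orc <- oracle_statement(scen)
    expect_equal(st$cost_total, orc$cost_total)
    expect_equal(st$revenue_total, orc$revenue_total)
    expect_equal(st$profit, orc$profit)
  }
})

test_that("ROI is scale-free and profit is monotone in product prices", {
  scen <- load_concept("III")
  base <- economic_statement(scen)
  for (k in c(0.5, 2, 7)) {
    prices_k <- scen$prices
    prices_k$price <- prices_k$price * k
    capex_k <- capex_spec(scen$capex$processing_investment * k,
                          scen$capex$biogas_investment_per_farm * k,
                          scen$capex$n_biogas_plants)
    opex_k <- scen$opex
    opex_k$salary <- opex_k$salary * k
    opex_k$logistics_rate <- opex_k$logistics_rate * k
    st_k <- economic_statement(scen, prices = prices_k, capex = capex_k,
                               opex = opex_k)
    expect_equal(st_k$profit, k * base$profit)
    expect_equal(st_k$roi, base$roi)
  }
  # raising only the sold-product prices raises profit
  up <- scen$prices
  sold <- up$item %in% c("oil", "fish_protein_concentrate", "meal")
  up$price[sold] <- up$price[sold] * 1.3
  expect_gt(economic_statement(scen, prices = up)$profit, base$profit)
})
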