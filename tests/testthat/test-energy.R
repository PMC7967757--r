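test_that("CHP output follows the feed mixture and the per-tonne basis", {
  spec <- load_concept("I")$biogas
  out <- chp_output(1, 5, spec)
  expect_equal(out$biogas, 528)            # 6 t x 88 m3/t
  expect_equal(out$methane, 528 * 0.65)
  expect_equal(out$electricity, 1213)
  expect_equal(out$heat, 1562)

  zero <- chp_output(0, 0, spec)
  expect_equal(unlist(zero), c(biogas = 0, methane = 0, heat = 0,
                               electricity = 0))
  expect_error(chp_output(-1, 5, spec), "non-negative")

  # linear scaling with residue throughput at the fixed mixing ratio
  twice <- chp_output(2, 10, spec)
  expect_equal(twice$biogas, 2 * out$biogas)
  expect_equal(twice$electricity, 2 * out$electricity)
  # off-ratio feeds are flagged, not rejected
  expect_warning(chp_output(1, 3, spec), "ratio")
})

test_that("biomass energy potential converts CHP output at 3.6 MJ/kWh", {
  expect_equal(biomass_energy(load_concept("I")$biogas), (1562 + 1213) * 3.6)
  expect_equal(biomass_energy(load_concept("I")$biogas), 9992,
               tolerance = 0.005)
  expect_equal(biomass_energy(load_concept("IV")$biogas), (203 + 158) * 3.6)
  expect_equal(biomass_energy(NULL), 0)
})

test_that("total energy input is the permutation-invariant ledger sum", {
  expect_equal(total_energy_input(load_concept("I")$energy_ledger), 2548)
  expect_equal(total_energy_input(
    energy_ledger(data.frame(operation = "x", direct = 10, indirect = 0))), 10)

  set.seed(17)
  entries <- data.frame(operation = paste0("op", 1:50),
                        direct = runif(50, 0, 800),
                        indirect = runif(50, 0, 200))
  led <- energy_ledger(entries)
  naive <- 0
  for (i in 1:50) naive <- naive + entries$direct[i] + entries$indirect[i]
  expect_equal(total_energy_input(led), naive)
  expect_equal(total_energy_input(energy_ledger(entries[sample(50), ])), naive)
})

test_that("the energy balance identity holds and degenerates safely", {
  ledI <- load_concept("I")$energy_ledger
  bal <- energy_balance(9992, ledI)
  expect_equal(bal$e_final, 9992 - 2548)      # 7444
  expect_equal(round(bal$ratio, 1), 3.9)

  # zero input: final energy is the biomass energy, ratio undefined
  led0 <- energy_ledger(data.frame(operation = "x", direct = 0, indirect = 0))
  b0 <- energy_balance(500, led0)
  expect_equal(b0$e_final, 500)
  expect_true(is.na(b0$ratio))

  cIV <- load_concept("IV")
  expect_equal(round(energy_balance(biomass_energy(cIV$biogas),
                                    cIV$energy_ledger)$ratio, 1), 1.0)

  # identity e_final + e_input = e_bm on random inputs
  set.seed(23)
  for (i in 1:20) {
    led <- energy_ledger(data.frame(operation = paste0("op", 1:4),
                                    direct = runif(4, 0, 1000),
                                    indirect = runif(4, 0, 300)))
    e_bm <- runif(1, 0, 12000)
    b <- energy_balance(e_bm, led)
    expect_equal(b$e_final + b$e_input, b$e_bm)
  }
})

test_that("CHP electricity stays below the methane chemical energy", {
  for (id in c("I", "IV")) {
    spec <- load_concept(id)$biogas
    out <- chp_output(spec$residue_input, spec$manure_input, spec)
    expect_lte((out$heat + out$electricity) * KWH_TO_MJ,
               out$methane * CH4_LHV_MJ_M3)
  }
  for (seed in 1:20) {
    scen <- generate_scenario(synthetic_scenario_spec(seed = seed))
    spec <- scen$biogas
    out <- chp_output(spec$residue_input, spec$manure_input, spec)
    expect_lte((out$heat + out$electricity) * KWH_TO_MJ,
               out$methane * CH4_LHV_MJ_M3)
  }
})

test_that("transport energy is linear in mass, distance and coefficient", {
  expect_equal(transport_energy(1, 100, 0.821), 82.1)
  expect_equal(transport_energy(1, 0), 0)
  expect_equal(transport_energy(2, 100), 2 * transport_energy(1, 100))
  expect_equal(transport_energy(3, 50, 0.5), 3 * 50 * 0.5)
  expect_error(transport_energy(-1, 100), "non-negative")
})

test_that("electricity balance nets generation against internal consumers", {
  cI <- load_concept("I")
  expect_equal(electricity_balance(cI$biogas$electricity_output,
                                   cI$electricity_consumers), 1042)
  cII <- load_concept("II")
  expect_equal(electricity_balance(0, cII$electricity_consumers), -41)
  expect_equal(electricity_balance(0, load_concept("III")$electricity_consumers),
               -51)
  expect_equal(electricity_balance(100, NULL), 100)
})

test_that("the energy report assembles the per-concept aggregates", {
  tab <- reference_energy_table()
  expect_equal(tab$processing_mj, c(82, 326, 377, 678))
  expect_equal(tab$transport_mj, rep(82.1, 4))
  expect_equal(tab$electricity_useful_kwh, c(1042, -41, -51, 66))
  expect_equal(tab$e_input_mj[tab$concept == "I"], 2548)
})
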