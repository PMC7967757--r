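test_that("stream coefficients and balances enforce their structural rules", {
  expect_error(stream_coefficient("x", "input", 1, "lb/tRM"), "unknown stream unit")
  expect_error(stream_coefficient("x", "input", -1, "kg/tRM"), "non-negative")

  base <- data.frame(name = "fish_costream", role = "input",
                     quantity = 1000, unit = "kg/tRM")
  # duplicate name within a role
  expect_error(
    process_balance("x", rbind(base,
      data.frame(name = "oil", role = "output", quantity = 10, unit = "kg/tRM"),
      data.frame(name = "oil", role = "output", quantity = 20, unit = "kg/tRM"))),
    "duplicate")
  # same name on both sides is fine (e.g. a recycle)
  expect_s3_class(
    process_balance("x", rbind(base,
      data.frame(name = "water", role = "input", quantity = 1, unit = "m3/tRM"),
      data.frame(name = "water", role = "output", quantity = 1, unit = "m3/tRM"))),
    "process_balance")
  # raw-material basis must be present as 1000 kg/tRM
  expect_error(
    process_balance("x", data.frame(name = "fish_costream", role = "input",
                                    quantity = 900, unit = "kg/tRM")),
    "1000 kg/tRM")
  # kg outputs must not exceed kg inputs
  expect_error(
    process_balance("x", rbind(base,
      data.frame(name = "oil", role = "output", quantity = 1100,
                 unit = "kg/tRM"))),
    "exceeds input mass")
})

test_that("annualization applies unit conversion and scales by capacity", {
  b3 <- load_concept("III")$balance
  fl <- annualize(b3, 10000)
  expect_equal(fl$annual[fl$stream == "oil"], 1870)           # 187 kg/tRM -> t/a
  expect_equal(fl$unit[fl$stream == "oil"], "t/a")
  expect_equal(fl$annual[fl$stream == "electricity"], 400000) # kWh/a
  expect_equal(fl$annual[fl$stream == "steam"], 7000)         # t/tRM kept in t

  expect_true(all(annualize(b3, 0)$annual == 0))
  expect_error(annualize(b3, -1), "non-negative")

  bad <- b3
  bad$streams$unit[1] <- "stone/tRM"
  expect_error(annualize(bad, 10), "unknown stream unit")
})

test_that("annualization matches a brute-force recomputation and is linear", {
  set.seed(401)
  units <- stream_units()
  streams <- rbind(
    data.frame(name = "fish_costream", role = "input", quantity = 1000,
               unit = "kg/tRM"),
    data.frame(name = paste0("in_", 1:5), role = "input",
               quantity = runif(5, 0, 50),
               unit = sample(units[-1], 5, replace = TRUE)),
    data.frame(name = paste0("out_", 1:6), role = "output",
               quantity = runif(6, 0, 100), unit = "kg/tRM"))
  b <- process_balance("rand", streams)
  fl <- annualize(b, 7321)
  for (i in seq_len(nrow(fl)))
    expect_equal(fl$annual[i],
                 oracle_annual(fl$per_tRM[i], b$streams$unit[i], 7321))
  # linearity in capacity
  for (k in c(0, 0.5, 2, 13)) {
    expect_equal(annualize(b, k * 7321)$annual, k * fl$annual)
  }
})

test_that("mass closure reads as product yield on the co-stream", {
  expect_equal(mass_closure(load_concept("II")$balance)$ratio, 1.0)
  expect_equal(mass_closure(load_concept("III")$balance)$ratio, 0.534)
  expect_error(process_balance("x", data.frame()), "columns")

  # permutation invariance
  b <- load_concept("IV")$balance
  set.seed(7)
  for (i in 1:5) {
    shuffled <- process_balance("IV", b$streams[sample(nrow(b$streams)), ])
    expect_identical(mass_closure(shuffled)$ratio, mass_closure(b)$ratio)
  }
})

test_that("scenario configs round-trip through JSON and YAML", {
  for (scen in list(load_concept("IV"), load_concept("II"),
                    generate_scenario(synthetic_scenario_spec(seed = 11)))) {
    flows <- annualize(scen$balance, scen$capacity)
    for (ext in c("json", "yaml")) {
      path <- withr::local_tempfile(fileext = paste0(".", ext))
      write_scenario(scen, path)
      back <- read_scenario(path)
      expect_equal(annualize(back$balance, back$capacity), flows,
                   tolerance = 1e-12)
      expect_equal(economic_statement(back)$profit,
                   economic_statement(scen)$profit, tolerance = 1e-12)
    }
  }
})

test_that("scenario validation ties the biogas branch to a residue stream", {
  cI <- load_concept("I")
  # dropping the plant while a residue remains is rejected
  expect_error(
    scenario_config("x", cI$balance, cI$capacity, cI$farm, cI$prices,
                    cI$capex, cI$opex, biogas = NULL),
    "residue stream")
  # attaching a plant to a residue-free balance is rejected
  cII <- load_concept("II")
  expect_error(
    scenario_config("x", cII$balance, cII$capacity, cII$farm, cII$prices,
                    cII$capex, cII$opex, biogas = cI$biogas),
    "no residue")
})
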