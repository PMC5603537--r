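test_that("substrate construction validates formulas and masses", {
  glc <- substrate("glucose")
  expect_equal(glc$n, 6L)
  expect_equal(glc$molar_mass, 6 * 12.011 + 12 * 1.008 + 6 * 15.999)
  expect_equal(glc$carbon_mass_fraction, 6 * 12.011 / glc$molar_mass)
  expect_equal(formula_string(glc), "C6H12O6")

  expect_error(substrate("unobtainium"), "unknown substrate")
  expect_error(substrate("x", n = 0, a = 4), "at least one carbon")
  expect_error(substrate("x", n = 2, a = 4.5), "non-negative integers")
  expect_error(substrate("glucose bad", n = 6, a = 12, b = 6,
                         molar_mass = 200), "0.1%")
  # a molar mass within 0.1% of the formula mass is accepted
  expect_silent(substrate("glucose ok", n = 6, a = 12, b = 6,
                          molar_mass = 180.2))
})

test_that("electron equivalents follow d = 4n + a - 2b - 3c", {
  expect_identical(electron_equivalents(substrate("glucose")), 24L)
  expect_identical(electron_equivalents(substrate("acetic acid")), 8L)
  expect_identical(electron_equivalents(substrate("biomass")), 20L)
  expect_identical(electron_equivalents(substrate("cellobiose")), 48L)
  # carbon dioxide has no oxidizable electrons; the error names the formula
  expect_error(electron_equivalents(substrate("carbon dioxide", n = 1, b = 2)),
               "CO2")
})

test_that("substrate COD is 8 g per electron equivalent", {
  expect_equal(substrate_cod(substrate("glucose")), 192)
  expect_equal(substrate_cod(substrate("acetate")), 64)
  expect_equal(substrate_cod(substrate("biomass")), 160)
})

test_that("the glucose reaction at fs = 0.2 reproduces the canonical coefficients", {
  rxn <- build_reaction(substrate("glucose"), partition_factors(0.2))
  co <- rxn$coefficients
  expect_equal(rxn$d, 24L)
  expect_equal(co[["ch4"]], 2.4)
  expect_equal(co[["co2"]], 2.64)
  expect_equal(co[["cells"]], 0.24)
  expect_equal(co[["nh4"]], -0.24)
  expect_equal(co[["hco3"]], -0.24)
  expect_equal(co[["water"]], 0.96)
  expect_lt(max(abs(reaction_balance(rxn))), 1e-9)
})

test_that("fs = 0 routes every electron to methane", {
  for (name in c("glucose", "xylose", "acetate")) {
    s <- substrate(name)
    rxn <- build_reaction(s, partition_factors(0))
    expect_equal(rxn$coefficients[["cells"]], 0)
    expect_equal(rxn$coefficients[["ch4"]], electron_equivalents(s) / 8)
  }
})

test_that("partition factors are validated", {
  expect_error(partition_factors(-0.1), "fs")
  expect_error(partition_factors(1.2), "fs")
  expect_error(partition_factors(0.3, 0.8), "sum")
  expect_error(build_reaction(substrate("glucose"), partition_factors(1.5)))
})

test_that("theoretical methane yields match the known sugar/acetate values", {
  f <- partition_factors(0.2)
  expect_equal(theoretical_ch4_yield(substrate("xylose"), f), 2.0)
  expect_equal(theoretical_ch4_yield(substrate("arabinose"), f), 2.0)
  expect_equal(theoretical_ch4_yield(substrate("acetic acid"), f), 0.8)
  expect_equal(theoretical_ch4_yield(substrate("glucose"), partition_factors(0)), 3.0)
})

test_that("biomass yield is 0.70625 fs g cells per g COD", {
  expect_equal(biomass_yield(partition_factors(0.2)), 0.14125)
  expect_equal(biomass_yield(partition_factors(0)), 0)
  expect_equal(signif(biomass_yield(partition_factors(1)), 3), 0.706)
})

test_that("conversion efficiency compares observed to theoretical methane", {
  glc <- substrate("glucose")
  expect_equal(conversion_efficiency(2.13, glc), 100 * 2.13 / 2.4)
  expect_equal(conversion_efficiency(0.4, substrate("acetate")), 50)
  expect_equal(conversion_efficiency(0, glc), 0)
  # complete basis uses the fs = 0 limit
  expect_equal(conversion_efficiency(1.5, glc, basis = "complete"), 50)
  expect_error(conversion_efficiency(1, glc, partition_factors(1)), "zero")
  expect_error(conversion_efficiency(-1, glc))
})

test_that("every random reaction balances elements, charge and electrons", {
  set.seed(42)
  for (i in 1:500) {
    s <- random_substrate()
    f <- partition_factors(stats::runif(1))
    rxn <- build_reaction(s, f)
    expect_lt(max(abs(reaction_balance(rxn))), 1e-9)
    # electron conservation: 8 e-eq per CH4, 20 per mol cells
    expect_equal(8 * rxn$coefficients[["ch4"]] + 20 * rxn$coefficients[["cells"]],
                 rxn$d)
  }
})

test_that("methane decreases and cells increase monotonically in fs", {
  s <- substrate("glucose")
  fs_grid <- seq(0, 1, by = 0.05)
  ch4 <- vapply(fs_grid, function(f)
    build_reaction(s, partition_factors(f))$coefficients[["ch4"]], numeric(1))
  cells <- vapply(fs_grid, function(f)
    build_reaction(s, partition_factors(f))$coefficients[["cells"]], numeric(1))
  expect_true(all(diff(ch4) < 0))
  expect_true(all(diff(cells) > 0))
})

test_that("molar yield converts to micromoles per gram substrate carbon", {
  glc <- substrate("glucose")
  expect_equal(theoretical_ch4_per_gC(glc, partition_factors(0)),
               3 / (6 * 12.011) * 1e6)
  # consistency between the per-mol and per-gC routes
  f <- partition_factors(0.2)
  expect_equal(theoretical_ch4_per_gC(glc, f) * 1e-6 * 6 * 12.011,
               theoretical_ch4_yield(glc, f))
})

test_that("reaction export moves negative coefficients to the reactant side", {
  rxn <- build_reaction(substrate("glucose"), partition_factors(0.2))
  tab <- reaction_coefficients(rxn)
  expect_setequal(tab$side[tab$coefficient < 0], "reactant")
  expect_setequal(tab$side[tab$coefficient > 0], "product")
  txt <- format(rxn)
  expect_match(txt, "->")
  expect_match(txt, "C6H12O6")
  expect_match(txt, "CH4")
  # the equation text keeps NH4+/HCO3- on the left for an N-free donor
  expect_match(strsplit(txt, "->")[[1]][1], "NH4\\+")
})
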