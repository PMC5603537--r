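sys25 <- carbonate_system()

test_that("ionization fractions follow the closed-form speciation", {
  a <- speciate_dic(sys25$pK1)
  expect_equal(a[["alpha0"]], a[["alpha1"]])
  expect_equal(speciate_dic(7)[["alpha1"]], 0.8168, tolerance = 5e-4)
  expect_gt(speciate_dic(3)[["alpha0"]], 0.999)
  expect_error(speciate_dic(0), "pH")
  expect_error(speciate_dic(15), "pH")

  # fractions lie in [0,1] and sum to 1 across the pH range
  a <- speciate_dic(seq(1, 13, length.out = 50))
  expect_true(all(a >= 0 & a <= 1))
  expect_lt(max(abs(rowSums(a) - 1)), 1e-12)
})

test_that("van't Hoff correction shifts constants the right way", {
  warm <- carbonate_system(temperature = 30, vant_hoff = TRUE)
  expect_gt(warm$pK2, warm$pK1)
  expect_lt(warm$pK1, sys25$pK1)        # dissociation strengthens with T
  expect_lt(warm$henry_kh, sys25$henry_kh) # CO2 less soluble when warm
  # without the flag the constants stay at their 25 degC values
  expect_equal(carbonate_system(temperature = 30)$pK1, sys25$pK1)
})

test_that("headspace mole fractions convert by the ideal gas law", {
  b <- bottle_config(substrate("glucose"), headspace_volume = 0.1,
                     buffer_mg_per_l = 1)
  expect_equal(gas_to_moles(0, b), 0)
  expect_equal(gas_to_moles(1, b), 0.1 / 24.4655 * 1e6, tolerance = 1e-4)
  expect_equal(gas_to_moles(0.5, b) * 2, gas_to_moles(1, b))
  b2 <- bottle_config(substrate("glucose"), headspace_volume = 0.2,
                      buffer_mg_per_l = 1)
  expect_equal(gas_to_moles(1, b2), 2 * gas_to_moles(1, b))
  expect_error(gas_to_moles(1.5, b), "\\[0, 1\\]")
})

test_that("dissolved inorganic carbon follows Henry plus speciation", {
  b <- bottle_config(substrate("glucose"), liquid_volume = 1,
                     buffer_mg_per_l = 1)
  expect_equal(dissolved_co2(0, 7, b), 0)
  # at pH = pK1 half the DIC is H2CO3*, so DIC doubles the Henry term
  expect_equal(dissolved_co2(0.1, sys25$pK1, b), 0.00339 / 0.5,
               tolerance = 1e-4)
  dic <- vapply(seq(5, 9, 0.5), function(p) dissolved_co2(0.1, p, b),
                numeric(1))
  expect_true(all(diff(dic) > 0))
})

test_that("inorganic carbon partitioning is the inverse of the forward model", {
  b <- bottle_config(substrate("glucose"), buffer_mg_per_l = 1)
  part <- partition_inorganic_carbon(0.002, 6.4, b)
  expect_equal(part$gas_mol + part$dic_mol, 0.002)
  expect_equal(gas_to_moles(part$p_co2 / b$headspace_pressure, b) * 1e-6,
               part$gas_mol)
  expect_equal(dissolved_co2(part$p_co2, 6.4, b), part$dic_mol)
})

test_that("the carbon ledger closes exactly for arbitrary inputs", {
  set.seed(21)
  b <- bottle_config(substrate("glucose"), buffer_mg_per_l = 1)
  for (i in 1:50) {
    rec <- list(day = sample(0:128, 1),
                ch4_frac = stats::runif(1, 0, 0.2),
                co2_frac = stats::runif(1, 0, 0.2),
                acetic_mM = stats::runif(1, 0, 15),
                formic_mM = stats::runif(1, 0, 3),
                lactic_mM = stats::runif(1, 0, 5),
                pH = stats::runif(1, 5.5, 7.5),
                substrate_mM = stats::runif(1, 0, 10))
    led <- carbon_ledger(rec, b)
    pools <- led$ch4_c + led$co2_gas_c + led$dic_c + led$buffer_c +
      led$acetic_c + led$formic_c + led$lactic_c + led$substrate_c +
      led$biomass_c
    expect_equal(pools, led$added_c)
  }
})

test_that("a stoichiometric glucose endpoint yields a biomass fraction of 0.2", {
  b <- bottle_config(substrate("glucose"), buffer_mg_per_l = 1)
  rec <- stoichiometric_endpoint_record(b, fs = 0.2, pH = 6.5)
  led <- carbon_ledger(rec, b)
  expect_true(led$closed)
  expect_equal(led$biomass_c / led$added_c, 0.2, tolerance = 0.02)
})

test_that("degenerate ledger inputs land where they should", {
  b <- bottle_config(substrate("glucose"), buffer_mg_per_l = 1)
  zero <- list(day = 0, ch4_frac = 0, co2_frac = 0, acetic_mM = 0,
               formic_mM = 0, lactic_mM = 0, pH = 6.8, substrate_mM = 10)
  led <- carbon_ledger(zero, b)
  # all added carbon sits in the residual substrate and buffer pools
  expect_equal(led$substrate_c + led$buffer_c, led$added_c)
  expect_equal(led$biomass_c, 0)
  expect_true(led$inorganic_deficit)

  expect_error(carbon_ledger(modifyList(zero, list(pH = NA)), b), "pH")
  expect_error(carbon_ledger(zero[-2], b), "missing")

  # when the measured pools exceed the added carbon (here: full residual
  # substrate plus a methane-rich headspace) the residual goes negative
  # and the closure flag trips
  blown <- modifyList(zero, list(ch4_frac = 0.9))
  led2 <- carbon_ledger(blown, b)
  expect_false(led2$closed)
  expect_lt(led2$biomass_c, 0)
})

test_that("ledger tables stack by day and pool without losing carbon", {
  b <- bottle_config(substrate("xylose"), buffer_mg_per_l = 1)
  recs <- data.frame(day = c(2, 46, 83, 128),
                     ch4_frac = c(0, 0.02, 0.05, 0.06),
                     co2_frac = c(0.01, 0.03, 0.04, 0.05),
                     acetic_mM = c(11, 7, 3, 6),
                     formic_mM = c(1.5, 0.7, 0.2, 0.8),
                     lactic_mM = c(3, 1, 0.3, 1),
                     pH = c(5.8, 6.3, 6.4, 6.5),
                     substrate_mM = c(0, 0, 0, 0))
  tab <- carbon_ledger_table(recs, b)
  expect_equal(nrow(tab), 4L)
  long <- ledger_long(tab)
  sums <- tapply(long$carbon_g, long$day, sum)
  expect_equal(as.numeric(sums), tab$added_c[order(tab$day)])
})
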