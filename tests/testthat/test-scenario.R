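test_that("the default ocean carries the atmosphere-proportioned N2 inventory", {
  s <- default_early_ocean()
  expect_equal(s$n2_moles / s$water_moles, 85000 / 5.56e7, tolerance = 1e-12)
  expect_identical(s$ammonia_fraction, 0)
  expect_equal(s$mg_molality / s$ca_molality, 5.14, tolerance = 0.02)
  comp <- build_composition(s)
  expect_identical(unname(comp$nitrogen_reduced), 0)
})

test_that("build_composition is exact salt arithmetic", {
  s <- default_early_ocean()
  s$total_phosphate <- 1e-5
  comp <- build_composition(s)
  b <- comp$element_totals
  kgw <- s$water_moles * 18.0153e-3
  # 4:1 NaH2PO4:Na2HPO4 -> (0.8*1 + 0.2*2) Na per P
  na_expected <- (s$na_molality + 1.2e-5) * kgw +
    2 * (1 - s$h2s_fraction) * s$sulfide_total * kgw
  expect_equal(b[["Na"]], na_expected, tolerance = 1e-12)
  expect_equal(b[["P"]], 1e-5 * kgw, tolerance = 1e-12)
  expect_equal(b[["Cl"]],
               (s$na_molality + 2 * s$mg_molality + 2 * s$ca_molality) * kgw,
               tolerance = 1e-12)
  expect_equal(b[["N"]], 2 * s$n2_moles, tolerance = 1e-12)
  # zero phosphate leaves no P at all
  s0 <- s; s0$total_phosphate <- 0
  expect_identical(unname(build_composition(s0)$element_totals[["P"]]), 0)
})

test_that("compositions are charge-neutral under the input oxidation states", {
  ox <- c(H = 1, O = -2, Na = 1, Cl = -1, Mg = 2, Ca = 2, S = -2, P = 5)
  for (f in c(0, 0.3, 1)) {
    s <- default_early_ocean(); s$ammonia_fraction <- f
    s$total_phosphate <- 1e-3
    comp <- build_composition(s)
    b <- comp$element_totals
    q <- sum(ox * b[names(ox)]) - 3 * comp$nitrogen_reduced
    expect_lt(abs(q), 1e-9 * sum(b))
  }
})

test_that("the Mg/Ca override re-partitions at fixed sum (or fixes Mg)", {
  s <- default_early_ocean()
  tot <- s$mg_molality + s$ca_molality
  s$mg_ca_ratio_override <- 10000
  b <- build_composition(s)$element_totals
  kgw <- s$water_moles * 18.0153e-3
  expect_equal(b[["Mg"]] / b[["Ca"]], 10000, tolerance = 1e-9)
  expect_equal((b[["Mg"]] + b[["Ca"]]) / kgw, tot, tolerance = 1e-12)
  s$mg_ca_fix_mg <- TRUE
  b2 <- build_composition(s)$element_totals
  expect_equal(b2[["Mg"]] / kgw, s$mg_molality, tolerance = 1e-12)
  expect_equal(b2[["Mg"]] / b2[["Ca"]], 10000, tolerance = 1e-9)
  s$mg_molality <- 0; s$ca_molality <- 0; s$mg_ca_fix_mg <- FALSE
  expect_error(build_composition(s), class = "protocean_bad_scenario")
})

test_that("ammonia_fraction endpoints move all nitrogen between pools", {
  s <- default_early_ocean()
  s$ammonia_fraction <- 0
  c0 <- build_composition(s)
  s$ammonia_fraction <- 1
  c1 <- build_composition(s)
  expect_identical(unname(c0$nitrogen_reduced), 0)
  expect_equal(c1$nitrogen_reduced, c1$element_totals[["N"]],
               tolerance = 1e-12)
  expect_equal(c0$element_totals[["N"]], c1$element_totals[["N"]],
               tolerance = 1e-12)
})

test_that("buffer calibration hits its target and respects capacity limits", {
  db <- pc_db()
  s <- calibrate_buffer(default_early_ocean(), db, target_pH = 7.75)
  st <- solve_equilibrium(build_composition(s), db)
  expect_equal(st$pH, 7.75, tolerance = 0.05)
  # Henderson-Hasselbalch with Na2S as a strong base: HS:H2S = 2(1-f):(2f-1)
  pka1 <- 6.9919
  ratio <- 2 * (1 - s$h2s_fraction) / (2 * s$h2s_fraction - 1)
  expect_equal(pka1 + log10(ratio), 7.75, tolerance = 0.1)

  s0 <- default_early_ocean()
  s0$sulfide_total <- 0; s0$ammonium_molality <- 0.1
  expect_error(calibrate_buffer(s0, db),
               class = "protocean_buffer_capacity")
  s1 <- default_early_ocean()
  s1$ammonium_molality <- 1; s1$sulfide_total <- 0.5
  expect_error(calibrate_buffer(s1, db, resize = FALSE),
               class = "protocean_buffer_capacity")
  expect_error(calibrate_buffer(default_early_ocean(), db, target_pH = 7.0),
               class = "protocean_bad_scenario")
})

test_that("the calibrated buffer holds pH across the full NH3 fraction sweep", {
  db <- pc_db()
  for (f in c(0, 0.5, 1)) {
    s <- default_early_ocean(); s$ammonia_fraction <- f
    st <- pc_solve_scenario(s, db)
    expect_true(st$pH >= 7.6 && st$pH <= 7.9)
  }
})

test_that("scenario validation rejects out-of-range fields", {
  expect_error(scenario_spec(ammonia_fraction = 1.2),
               class = "protocean_bad_scenario")
  expect_error(scenario_spec(total_phosphate = -1),
               class = "protocean_bad_scenario")
  expect_error(scenario_spec(water_moles = 0),
               class = "protocean_bad_scenario")
})
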