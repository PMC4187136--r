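test_that("pure water solves to neutral pH with equal H+ and OH-", {
  st <- solve_equilibrium(comp_pure_water(), pc_db())
  expect_equal(st$pH, 13.998 / 2, tolerance = 1e-4)
  expect_equal(st$molalities[["H+"]], st$molalities[["OH-"]],
               tolerance = 1e-9)
  expect_length(st$solid_assemblage, 0)
  expect_length(st$gas_partial_pressures, 0)
})

test_that("a 4:1 phosphate buffer matches the closed-form proton condition", {
  db <- pc_db()
  st <- solve_equilibrium(comp_phosphate_buffer(), db)
  # independent oracle: root of the proton condition with the database pKa's
  lk <- function(r) reaction_logK(db, reaction(r))
  k1 <- 10^lk(c("H3PO4(aq)" = -1, "H+" = 1, "H2PO4-" = 1))
  k2 <- 10^lk(c("H2PO4-" = -1, "H+" = 1, "HPO4-2" = 1))
  k3 <- 10^lk(c("HPO4-2" = -1, "H+" = 1, "PO4-3" = 1))
  kw <- 10^lk(c("H2O(l)" = -1, "H+" = 1, "OH-" = 1))
  ptot <- 0.01; na <- 0.012
  f <- function(h) {
    den <- h^3 + h^2 * k1 + h * k1 * k2 + k1 * k2 * k3
    frac <- c(h^2 * k1, h * k1 * k2, k1 * k2 * k3) / den  # charges 1..3
    h + na - kw / h - ptot * sum(frac * 1:3)
  }
  h_star <- uniroot(f, c(1e-10, 1e-3), tol = 1e-18)$root
  expect_equal(st$pH, -log10(h_star), tolerance = 1e-6)
  # and the textbook two-species value, exact to the buffer approximation
  expect_equal(st$pH, 7.2057 + log10(0.2 / 0.8), tolerance = 1e-3)
})

test_that("the early ocean at high Mg/Ca and ample ammonium precipitates struvite", {
  st <- pc_solve_scenario(scenario_mgca(10000, ammonium = 0.2), pc_db())
  expect_true("Struvite" %in% st$solid_assemblage)
  expect_gt(st$species_moles[["Struvite"]], 1e-12)
  expect_true(st$pH > 7.6 && st$pH < 7.9)
})

test_that("saturation index is the hand-computed IAP/Ksp on a synthetic state", {
  db <- pc_db()
  # synthetic dissolved state: Mg = NH4 = PO4 = 1e-3 mol/kg
  st <- structure(list(
    molalities = c("H+" = 1e-7, "Mg+2" = 1e-3, "NH4+" = 1e-3,
                   "PO4-3" = 1e-3),
    gas_partial_pressures = setNames(numeric(0), character(0)),
    species_moles = c("H2O(l)" = 55.5084),
    mode = "fixed"), class = "equilibrium_state")
  # IAP = 1e-9, pKsp = 12.60 -> SI = -9 + 12.60 (to the 3-decimal dGf grid)
  expect_equal(saturation_index(st, "Struvite", db), 3.60, tolerance = 1e-4)
  expect_error(saturation_index(st, "NH4+", db),
               class = "protocean_not_a_solid")
})

test_that("solved states carry SI = 0 on present solids, <= 0 on absent ones", {
  db <- pc_db()
  st <- pc_solve_scenario(scenario_mgca(10000, ammonium = 0.2), db)
  for (s in st$solid_assemblage)
    expect_equal(saturation_index(st, s, db), 0, tolerance = 1e-6)
  absent <- setdiff(intersect(db$species$name[db$species$phase_class == "solid"],
                              st$active_species), st$solid_assemblage)
  for (s in absent)
    expect_lte(saturation_index(st, s, db), 1e-6)
})

test_that("modern-seawater Mg/Ca never saturates struvite at any ammonia fraction", {
  db <- pc_db()
  for (f in c(0.25, 0.5, 1)) {
    s <- default_early_ocean(); s$ammonia_fraction <- f
    st <- pc_solve_scenario(s, db)
    expect_false(struvite_present(st))
    expect_lt(saturation_index(st, "Struvite", db), 0)
  }
})

test_that("ammonia gas equilibrium follows the N2/H2 mass action law", {
  db <- pc_db()
  expect_identical(ammonia_redox_equilibrium(1, 0, db), 0)
  expect_identical(ammonia_redox_equilibrium(0, 1, db), 0)
  # pN2 = pH2 = 1 bar: K from the shipped NH3(g) formation energy
  expect_equal(ammonia_redox_equilibrium(1, 1, db), 761.93, tolerance = 1e-3)
  # monotone in both arguments, and the 1/2, 3/2 exponents
  p <- ammonia_redox_equilibrium(c(1, 4, 1), c(1, 1, 4), db)
  expect_equal(p[2] / p[1], 2, tolerance = 1e-12)
  expect_equal(p[3] / p[1], 8, tolerance = 1e-12)
})

test_that("imposing a higher H2 fugacity drives the ocean into the struvite field", {
  db <- pc_db()
  s <- scenario_mgca(10000); s$n2_moles <- 0.25
  present <- logical(0)
  for (ph2 in c(1e-8, 1e-6, 1e-4)) {
    s$h2_partial_pressure <- ph2
    st <- pc_solve_scenario(s, db)
    present <- c(present, struvite_present(st))
    expect_true(st$pH > 7.6 && st$pH < 7.9)
  }
  expect_identical(present, c(FALSE, FALSE, TRUE))   # monotone entry
})

test_that("verify_state certifies solver output and flags a corrupted state", {
  db <- pc_db()
  spec <- calibrate_buffer(scenario_mgca(10000, ammonium = 0.2), db)
  comp <- build_composition(spec)
  st <- solve_equilibrium(comp, db)
  vr <- verify_state(st, comp, db)
  expect_true(attr(vr, "ok"))
  el <- vr$residual[vr$check == "element-balance"]
  expect_lt(max(abs(el)), 1e-9)
  expect_lt(abs(vr$residual[vr$check == "charge-balance"]), 1e-12)

  # move the struvite mole into dissolved ions: balances survive but the
  # mass-action/complementarity structure must break
  bad <- st
  n_str <- bad$species_moles[["Struvite"]]
  W <- bad$water_moles * 18.0153e-3
  bad$species_moles[["Struvite"]] <- 0
  bad$solid_assemblage <- setdiff(bad$solid_assemblage, "Struvite")
  for (sp in c("Mg+2", "NH4+", "PO4-3"))
    bad$molalities[[sp]] <- bad$molalities[[sp]] + n_str / W
  vr2 <- verify_state(bad, comp, db)
  expect_false(attr(vr2, "ok"))
})

test_that("zero-total elements are pruned and infeasible input is rejected", {
  db <- pc_db()
  s <- default_early_ocean(); s$total_phosphate <- 0
  st <- pc_solve_scenario(s, db, calibrate = FALSE)
  expect_false(any(grepl("PO4|P2O7", names(st$species_moles))))
  expect_error(solver_options(si_tol = 0), class = "protocean_bad_options")
  expect_error(solver_options(mode = "h2"), class = "protocean_bad_options")
  expect_error(solver_options(reduced_p = TRUE),
               class = "protocean_bad_options")
  expect_error(system_composition(c(H = 2, O = 1, Na = -1)),
               class = "protocean_bad_composition")
})

test_that("struvite moles respond monotonically to ammonium and magnesium", {
  db <- pc_db()
  # ammonium ramp at high Mg/Ca
  moles <- vapply(10^seq(log10(0.05), log10(2), length.out = 10),
                  function(a) {
                    st <- pc_solve_scenario(scenario_mgca(1e4, ammonium = a),
                                            db)
                    if (struvite_present(st))
                      st$species_moles[["Struvite"]] else 0
                  }, numeric(1))
  expect_true(all(diff(moles) >= -1e-12))
  expect_gt(moles[10], moles[1])
  # magnesium ramp in a Mg-limited regime (phosphate and ammonium ample)
  moles2 <- vapply(10^seq(-5, -3.5, length.out = 10), function(mg) {
    s <- default_early_ocean()
    s$mg_molality <- mg; s$ca_molality <- 1e-8
    s$ammonium_molality <- 0.5
    s$total_phosphate <- 1e-3
    st <- pc_solve_scenario(s, db)
    if (struvite_present(st)) st$species_moles[["Struvite"]] else 0
  }, numeric(1))
  expect_true(all(diff(moles2) >= -1e-12))
  expect_gt(moles2[10], 0)
})
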