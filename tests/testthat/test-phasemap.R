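test_that("assemblage classification separates phosphate solids from oxides", {
  db <- pc_db()
  st <- solve_equilibrium(comp_pure_water(), db)
  expect_identical(as.character(classify_assemblage(st, db)), "none")
  st2 <- pc_solve_scenario(scenario_mgca(10000, ammonium = 0.2), db)
  expect_identical(as.character(classify_assemblage(st2, db)), "Struvite")
})

test_that("axis specifications are validated", {
  expect_error(axis_spec("mg_ca_ratio", 10, 5), class = "protocean_bad_axis")
  expect_error(axis_spec("mg_ca_ratio", 0, 5), class = "protocean_bad_axis")
  expect_error(axis_spec("nonsense", 1, 5), class = "protocean_bad_axis")
  ax <- axis_spec("total_phosphate", 1e-6, 1e-2, n = 5)
  expect_length(ax$values, 5)
  expect_equal(ax$values[3], 1e-4, tolerance = 1e-12)
})

test_that("a sweep over an undersaturated region is all 'none' and deterministic", {
  db <- pc_db()
  # seawater Mg/Ca with phosphate far below even apatite saturation
  tmpl <- default_early_ocean()
  tmpl$total_phosphate <- 1e-11
  ax1 <- axis_spec("ammonium_molality", 1e-4, 1e-3, n = 2)
  ax2 <- axis_spec("total_phosphate", 1e-12, 1e-11, n = 2)
  m1 <- sweep_phasemap(tmpl, ax1, ax2, db)
  expect_identical(nrow(m1$grid), 4L)
  expect_true(all(m1$grid$label == "none"))
  expect_true(all(m1$grid$status == "ok"))
  m2 <- sweep_phasemap(tmpl, ax1, ax2, db)
  expect_identical(m1$grid, m2$grid)   # bit-identical re-run
  expect_error(sweep_phasemap(tmpl, ax1, ax1, db),
               class = "protocean_bad_axis")
})

test_that("grid cells are independent: a sweep equals its recomputed rows", {
  db <- pc_db()
  tmpl <- scenario_mgca(10000)
  ax1 <- axis_spec("ammonium_molality", 0.03, 0.3, n = 3)
  ax2 <- axis_spec("total_phosphate", 1e-6, 1e-4, n = 3)
  m <- sweep_phasemap(tmpl, ax1, ax2, db)
  for (j in c(1L, 3L)) {
    row <- sweep_phasemap(tmpl, ax1,
                          axis_spec("total_phosphate", ax2$values[j],
                                    ax2$values[j] * (1 + 1e-12), n = 2), db)
    sub <- m$grid[m$grid$total_phosphate == ax2$values[j], ]
    keep <- row$grid$total_phosphate == min(row$grid$total_phosphate)
    expect_identical(sub$label, row$grid$label[keep])
    expect_equal(sub$struvite_mol, row$grid$struvite_mol[keep],
                 tolerance = 1e-9)
  }
})

test_that("bisection finds an analytically known phosphate threshold", {
  db <- pc_db()
  # predicate on the input phosphate total itself: flips at 3e-5 exactly
  kgw <- 1
  pred <- function(st) st$composition$element_totals[["P"]] / kgw >= 3e-5
  th <- find_threshold(default_early_ocean(), "total_phosphate", pred,
                       c(1e-5, 1e-4), tol = 1e-3, db = db)
  expect_equal(th$threshold, 3e-5, tolerance = 2e-3)
  expect_lte(th$width, 1e-3)
  expect_true(th$bracket[1] <= th$threshold & th$threshold <= th$bracket[2])
})

test_that("a bracket whose ends agree raises a bracket error", {
  db <- pc_db()
  expect_error(
    find_threshold(default_early_ocean(), "ammonium_molality",
                   function(st) TRUE, c(1e-3, 1e-2), db = db),
    class = "protocean_bracket_error")
})

test_that("struvite presence is monotone along an ammonium sweep row", {
  db <- pc_db()
  tmpl <- scenario_mgca(10000)
  pres <- vapply(10^seq(-3, 0, length.out = 8), function(a) {
    struvite_present(pc_solve_scenario(scenario_mgca(10000, ammonium = a),
                                       db))
  }, logical(1))
  expect_true(all(diff(as.integer(pres)) >= 0))   # absent -> present once
  expect_false(pres[1]); expect_true(pres[8])
})

test_that("threshold results are bracketed by the nearest discordant sweep cells", {
  db <- pc_db()
  tmpl <- scenario_mgca(10000)
  ax <- axis_spec("ammonium_molality", 1e-2, 1, n = 7)
  pres <- vapply(ax$values, function(a)
    struvite_present(pc_solve_scenario(scenario_mgca(10000, ammonium = a),
                                       db)), logical(1))
  th <- find_threshold(tmpl, "ammonium_molality", struvite_present,
                       c(1e-2, 1), db = db)
  i <- max(which(!pres))
  expect_gte(th$threshold, ax$values[i])
  expect_lte(th$threshold, ax$values[i + 1])
})

test_that("phase maps round-trip through CSV byte-identically", {
  db <- pc_db()
  tmpl <- default_early_ocean(); tmpl$total_phosphate <- 1e-7
  m <- sweep_phasemap(tmpl, axis_spec("ammonium_molality", 1e-4, 1e-3, n = 2),
                      axis_spec("total_phosphate", 1e-12, 1e-11, n = 2), db)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  export_phasemap(m, f1)
  m2 <- read_phasemap(f1)
  export_phasemap(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(m2$grid$pH, m$grid$pH, tolerance = 1e-15)
  expect_identical(m2$axis1$parameter, "ammonium_molality")
})
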