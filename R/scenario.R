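#' Construct a scenario specification
#'
#' A `scenario_spec` is the recipe for one model-ocean composition: water
#' and headspace inventory, seawater-derived Na/Mg/Ca (charge-balanced by
#' Cl-), phosphate added as NaH2PO4:Na2HPO4 in a fixed 4:1 mole ratio, a
#' sulfide (H2S/Na2S) pH buffer, and nitrogen supplied either as an
#' NH3-fraction of the N2 inventory or as an explicit ammonium molality
#' (the swept ammonium axis extends beyond the atmospheric N inventory,
#' which is why an explicit override exists).
#'
#' @param water_moles moles of solvent water (55.508 mol = 1 kg basis).
#' @param n2_moles moles of N2 gas in the headspace inventory.
#' @param ammonia_fraction fraction (0-1) of total N supplied as NH3.
#' @param ammonium_molality optional explicit reduced-N molality (mol/kg);
#'   when set it overrides `ammonia_fraction` and leaves the N2 inventory
#'   untouched.
#' @param na_molality,mg_molality,ca_molality seawater major ions, mol/kg.
#' @param mg_ca_ratio_override optional Mg/Ca molar ratio; re-partitions
#'   Mg+Ca at fixed sum (or fixes Mg and shrinks Ca if
#'   `mg_ca_fix_mg = TRUE`).
#' @param mg_ca_fix_mg alternative override mode (sensitivity check).
#' @param total_phosphate total P, mol/kg, split 4:1 NaH2PO4:Na2HPO4.
#' @param sulfide_total total sulfide buffer loading, mol/kg.
#' @param h2s_fraction H2S share of the sulfide buffer (rest is Na2S).
#' @param h2_partial_pressure optional imposed H2 pressure, bar
#'   (h2-coupled mode).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(water_moles = 1 / PC_M_WATER,
                          n2_moles = (1 / PC_M_WATER) * 85000 / 5.56e7,
                          ammonia_fraction = 0,
                          ammonium_molality = NULL,
                          na_molality = 0.4686,
                          mg_molality = 0.05282,
                          ca_molality = 0.01028,
                          mg_ca_ratio_override = NULL,
                          mg_ca_fix_mg = FALSE,
                          total_phosphate = 1e-5,
                          sulfide_total = 7.0,
                          h2s_fraction = 0.5673,
                          h2_partial_pressure = NULL) {
  num <- c(water_moles = water_moles, n2_moles = n2_moles,
           ammonia_fraction = ammonia_fraction, na_molality = na_molality,
           mg_molality = mg_molality, ca_molality = ca_molality,
           total_phosphate = total_phosphate, sulfide_total = sulfide_total,
           h2s_fraction = h2s_fraction)
  if (any(num < 0))
    pc_stop("protocean_bad_scenario", "negative quantity: %s",
            paste(names(num)[num < 0], collapse = ", "))
  if (ammonia_fraction > 1)
    pc_stop("protocean_bad_scenario", "ammonia_fraction must be in [0, 1]")
  if (h2s_fraction > 1)
    pc_stop("protocean_bad_scenario", "h2s_fraction must be in [0, 1]")
  if (water_moles <= 0)
    pc_stop("protocean_bad_scenario", "water_moles must be positive")
  structure(list(water_moles = water_moles, n2_moles = n2_moles,
                 ammonia_fraction = ammonia_fraction,
                 ammonium_molality = ammonium_molality,
                 na_molality = na_molality, mg_molality = mg_molality,
                 ca_molality = ca_molality,
                 mg_ca_ratio_override = mg_ca_ratio_override,
                 mg_ca_fix_mg = mg_ca_fix_mg,
                 total_phosphate = total_phosphate,
                 sulfide_total = sulfide_total,
                 h2s_fraction = h2s_fraction,
                 h2_partial_pressure = h2_partial_pressure,
                 phosphate_split = c(NaH2PO4 = 0.8, Na2HPO4 = 0.2)),
            class = "scenario_spec")
}

#' Default early-ocean scenario
#'
#' One kilogram of ocean water (55.508 mol) carrying the atmosphere-derived
#' N2 inventory in the proportion 85,000 mol N2 : 5.56e7 mol H2O, seawater
#' Na/Mg/Ca (0.4686 / 0.05282 / 0.01028 mol/kg, Cl- as the balancing
#' anion), 1e-5 mol/kg total phosphate as the 4:1 salt mix, and an excess
#' sulfide buffer split for pH 7.8. All nitrogen starts as N2
#' (`ammonia_fraction = 0`), the baseline of the 0-100% NH3 sweep.
#'
#' @return a `scenario_spec`.
#' @export
default_early_ocean <- function() scenario_spec()

#' Build the bulk composition a scenario implies
#'
#' Pure arithmetic: sums the element contributions of water, N2/NH3, NaCl,
#' MgCl2, CaCl2, the 4:1 phosphate salts and the H2S/Na2S buffer. The
#' result is charge-neutral by construction.
#'
#' @param spec a `scenario_spec`.
#' @return a [system_composition()].
#' @export
build_composition <- function(spec) {
  kgw <- spec$water_moles * PC_M_WATER
  mg <- spec$mg_molality; ca <- spec$ca_molality
  if (!is.null(spec$mg_ca_ratio_override)) {
    r <- spec$mg_ca_ratio_override
    if (spec$mg_ca_fix_mg) {
      if (mg <= 0) pc_stop("protocean_bad_scenario",
                           "mg_ca ratio override with zero Mg total")
      ca <- mg / r
    } else {
      s <- mg + ca
      if (s <= 0) pc_stop("protocean_bad_scenario",
                          "mg_ca ratio override with zero Mg+Ca total")
      mg <- s * r / (1 + r); ca <- s / (1 + r)
    }
  }
  p_mol <- spec$total_phosphate * kgw
  s_mol <- spec$sulfide_total * kgw
  h2s <- spec$h2s_fraction * s_mol
  na2s <- s_mol - h2s
  if (!is.null(spec$ammonium_molality)) {
    nr <- spec$ammonium_molality * kgw
    nn <- 2 * spec$n2_moles
  } else {
    tot_n <- 2 * spec$n2_moles
    nr <- spec$ammonia_fraction * tot_n
    nn <- tot_n - nr
  }
  split <- spec$phosphate_split  # 4:1 NaH2PO4 : Na2HPO4 by construction
  totals <- c(
    H = 2 * spec$water_moles + (2 * split[["NaH2PO4"]] +
                                  1 * split[["Na2HPO4"]]) * p_mol +
      2 * h2s + 3 * nr,
    O = spec$water_moles + 4 * p_mol,
    Na = spec$na_molality * kgw +
      (split[["NaH2PO4"]] + 2 * split[["Na2HPO4"]]) * p_mol + 2 * na2s,
    Cl = (spec$na_molality + 2 * mg + 2 * ca) * kgw,
    Mg = mg * kgw, Ca = ca * kgw,
    N = nr + nn, S = s_mol, P = p_mol)
  system_composition(totals, nitrogen_reduced = nr)
}

#' Calibrate the sulfide pH buffer of a scenario
#'
#' Sizes the H2S/Na2S buffer so the solved pH hits `target_pH` and so the
#' scenario's own reduced-nitrogen and phosphate loads cannot push pH more
#' than ~0.1 away: the sulfide total is set to an excess proportional to
#' the acid/base load (factor 40, floor 1 mol/kg), and the H2S:Na2S split
#' is then tuned against full equilibrium solves.
#'
#' @param spec a `scenario_spec`; @param db a `thermo_db`.
#' @param target_pH target, must lie in the buffered band \[7.6, 7.9\].
#' @param resize if `FALSE`, keep `spec$sulfide_total` and fail when its
#'   capacity is insufficient for the scenario's NH3 load.
#' @return the calibrated `scenario_spec`.
#' @export
calibrate_buffer <- function(spec, db = default_thermodb(), target_pH = 7.8,
                             resize = TRUE) {
  if (target_pH < 7.6 || target_pH > 7.9)
    pc_stop("protocean_bad_scenario",
            "target_pH %.2f outside the buffered band [7.6, 7.9]", target_pH)
  kgw <- spec$water_moles * PC_M_WATER
  nr <- if (!is.null(spec$ammonium_molality)) spec$ammonium_molality
        else spec$ammonia_fraction * 2 * spec$n2_moles / kgw
  if (!is.null(spec$h2_partial_pressure)) {
    # h2-coupled mode: ammonium forms from N2 + H2; bound the load by the
    # N inventory and the imposed-fugacity equilibrium ammonium
    pnh3 <- ammonia_redox_equilibrium(1, spec$h2_partial_pressure, db)
    lkh <- reaction_logK(db, reaction(c("NH3(g)" = -1, "NH3(aq)" = 1)))
    pkn <- -reaction_logK(db, reaction(c("NH4+" = -1, "H+" = 1,
                                         "NH3(aq)" = 1)))
    tot_n <- 2 * spec$n2_moles / kgw + nr
    nr <- min(tot_n, pnh3 * 10^lkh * 10^(pkn - target_pH))
  }
  load <- nr + 0.6 * spec$total_phosphate
  need <- max(1.0, 40 * load)
  if (spec$sulfide_total <= 0 && load > 0)
    pc_stop("protocean_buffer_capacity",
            "no sulfide buffer but an NH3/phosphate load of %.3g mol/kg", load)
  if (!resize && spec$sulfide_total < 25 * load)
    pc_stop("protocean_buffer_capacity",
            "sulfide_total %.3g mol/kg below the capacity (%.3g) needed for the NH3 load",
            spec$sulfide_total, 25 * load)
  if (resize) spec$sulfide_total <- max(spec$sulfide_total, need)

  pka1 <- -reaction_logK(db, reaction(c("H2S(aq)" = -1, "H+" = 1, "HS-" = 1)))
  # Na2S acts as a strong base (no S-2 in the ladder: S-2 + H2O -> HS- + OH-,
  # and the OH- deprotonates H2S), so with H2S fraction f the equilibrium
  # ratio is HS-:H2S = 2(1-f) : (2f-1); invert Henderson-Hasselbalch for f
  r <- 10^(target_pH - pka1)
  f0 <- (r + 2) / (2 * r + 2)
  sopts <- if (!is.null(spec$h2_partial_pressure))
    solver_options(mode = "h2", h2_partial_pressure = spec$h2_partial_pressure)
  else solver_options()
  ph_at <- function(f) {
    s <- spec; s$h2s_fraction <- f
    solve_equilibrium(build_composition(s), db, sopts)$pH
  }
  f <- f0
  ph <- ph_at(f)
  # secant refinement on the split (the analytic start is already close)
  f1 <- min(max(f0 * 10^(ph - target_pH), 1e-4), 1 - 1e-4)
  for (k in 1:8) {
    if (abs(ph - target_pH) < 0.005) break
    ph1 <- ph_at(f1)
    if (abs(ph1 - ph) < 1e-12) break
    f2 <- f1 + (target_pH - ph1) * (f1 - f) / (ph1 - ph)
    f <- f1; ph <- ph1
    f1 <- min(max(f2, 1e-4), 1 - 1e-4)
  }
  if (abs(ph - target_pH) >= 0.05) { f <- f1; ph <- ph_at(f1) }
  if (abs(ph - target_pH) >= 0.05)
    pc_stop("protocean_buffer_capacity",
            "buffer calibration missed target %.2f (got %.3f)", target_pH, ph)
  spec$h2s_fraction <- f
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  kgw <- x$water_moles * PC_M_WATER
  cat("<scenario_spec>\n")
  cat(sprintf("  water %.3f mol (%.3f kg) | N2 %.4g mol\n",
              x$water_moles, kgw, x$n2_moles))
  cat(sprintf("  Na %.4g Mg %.4g Ca %.4g mol/kg%s\n", x$na_molality,
              x$mg_molality, x$ca_molality,
              if (!is.null(x$mg_ca_ratio_override))
                sprintf(" | Mg/Ca override %g", x$mg_ca_ratio_override) else ""))
  cat(sprintf("  P %.3g mol/kg (4:1 salts) | sulfide %.3g mol/kg (H2S frac %.3f)\n",
              x$total_phosphate, x$sulfide_total, x$h2s_fraction))
  cat(sprintf("  ammonia_fraction %.3g%s%s\n", x$ammonia_fraction,
              if (!is.null(x$ammonium_molality))
                sprintf(" | ammonium %.3g mol/kg", x$ammonium_molality) else "",
              if (!is.null(x$h2_partial_pressure))
                sprintf(" | pH2 %.3g bar", x$h2_partial_pressure) else ""))
  invisible(x)
}

# Internal: return spec with one sweepable parameter set.
pc_set_param <- function(spec, param, value) {
  switch(param,
         mg_ca_ratio = { spec$mg_ca_ratio_override <- value },
         ammonium_molality = { spec$ammonium_molality <- value },
         total_phosphate = { spec$total_phosphate <- value },
         h2_partial_pressure = { spec$h2_partial_pressure <- value },
         ammonia_fraction = { spec$ammonia_fraction <- value },
         pc_stop("protocean_bad_axis", "unknown sweep parameter '%s'", param))
  spec
}

# Internal: solve one scenario point (recalibrating its buffer) and return
# the equilibrium state. Used by sweeps, thresholds and the CLI.
pc_solve_scenario <- function(spec, db = default_thermodb(),
                              opts = NULL, target_pH = 7.8,
                              calibrate = TRUE) {
  if (is.null(opts)) {
    opts <- if (!is.null(spec$h2_partial_pressure))
      solver_options(mode = "h2",
                     h2_partial_pressure = spec$h2_partial_pressure)
    else solver_options()
  }
  if (calibrate) spec <- calibrate_buffer(spec, db, target_pH)
  solve_equilibrium(build_composition(spec), db, opts)
}
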