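# Brute-force Gibbs-energy oracle for the reduced struvite system:
# water, H+, OH-, Mg+2, NH4+, HPO4-2, PO4-3 and the struvite solid.
# Minimises total G over a refined dense grid of extents of the three
# independent reactions (water ionisation, HPO4 deprotonation, struvite
# formation), entirely independent of the package's Newton solver.

oracle_reduced_set <- c("H+", "OH-", "Mg+2", "NH4+", "HPO4-2", "PO4-3",
                        "Struvite")

# reference amounts (mol): interior, charge-neutral starting point
oracle_reference <- function(b_mg = 1e-3, b_n = 1e-3, b_hpo4 = 1.47e-3,
                             b_po4 = 2e-5) {
  c(nw = 1 / 18.0153e-3, "Mg+2" = b_mg, "NH4+" = b_n, "HPO4-2" = b_hpo4,
    "PO4-3" = b_po4, "H+" = 1e-7, "OH-" = 1e-7, Struvite = 0)
}

oracle_gibbs_grid <- function(db, n0 = oracle_reference(),
                              levels = 9, npts = 11) {
  RT <- 8.314462618e-3 * 298.15
  Mw <- 18.0153e-3
  g <- setNames(db$species[names(n0)[-1], "dGf"], names(n0)[-1])
  g_w <- db$species["H2O(l)", "dGf"]
  # reaction extents: columns over (nw, solutes..., struvite)
  S <- cbind(
    ionise = c(nw = -1, "Mg+2" = 0, "NH4+" = 0, "HPO4-2" = 0, "PO4-3" = 0,
               "H+" = 1, "OH-" = 1, Struvite = 0),
    deprot = c(nw = 0, "Mg+2" = 0, "NH4+" = 0, "HPO4-2" = -1, "PO4-3" = 1,
               "H+" = 1, "OH-" = 0, Struvite = 0),
    struv  = c(nw = -6, "Mg+2" = -1, "NH4+" = -1, "HPO4-2" = 0, "PO4-3" = -1,
               "H+" = 0, "OH-" = 0, Struvite = 1))
  # Molality-scale ideal-dilute Gibbs functional. The -RT per solute mole
  # is required for variational consistency: with unit water activity the
  # plain sum of n*mu is not a potential (Gibbs-Duhem), whereas this
  # functional's stationary points are exactly the molality mass-action
  # laws the package solves. Solvent mass is held at the reference
  # kilogram (solute-induced drift ~1e-6 relative, far below tolerance).
  W0 <- n0[["nw"]] * Mw
  solutes <- setdiff(names(g), "Struvite")
  total_G <- function(n) {
    if (any(n < 0)) return(Inf)
    sol <- n[solutes]
    lnm <- ifelse(sol > 0, log(pmax(sol / W0, 1e-300)), 0)
    n[["nw"]] * g_w + sum(sol * (g[solutes] - RT + RT * lnm)) +
      n[["Struvite"]] * g[["Struvite"]]
  }
  centre <- c(0, 0, 0)
  width <- c(1e-3, 1e-3, 1e-3)
  best <- list(G = total_G(n0), xi = centre)
  for (lev in seq_len(levels)) {
    grid <- expand.grid(x1 = seq(-1, 1, length.out = npts),
                        x2 = seq(-1, 1, length.out = npts),
                        x3 = seq(-1, 1, length.out = npts))
    for (r in seq_len(nrow(grid))) {
      xi <- centre + width * as.numeric(grid[r, ])
      G <- total_G(n0 + drop(S %*% xi))
      if (G < best$G) best <- list(G = G, xi = xi)
    }
    centre <- best$xi
    width <- width * 2.2 / (npts - 1)   # keep the old best inside new box
  }
  n <- n0 + drop(S %*% best$xi)
  list(G = best$G, n = n, resolution = width)
}

# solve the same reduced system with the package solver
oracle_solver_state <- function(db, n0 = oracle_reference()) {
  A <- db$formula[names(n0)[-1], , drop = FALSE]
  b <- drop(n0[-1] %*% A)
  b["H"] <- b["H"] + 2 * n0[["nw"]]
  b["O"] <- b["O"] + n0[["nw"]]
  comp <- system_composition(b[b > 0], nitrogen_reduced = b[["N"]])
  keep <- c(oracle_reduced_set, "H2O(l)")
  opts <- solver_options(active_exclude = setdiff(db$species$name, keep))
  solve_equilibrium(comp, db, opts)
}
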