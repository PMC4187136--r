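#' Solver options
#'
#' Tolerances and mode switches for [solve_equilibrium()].
#'
#' @param element_tol relative element-balance tolerance (verification).
#' @param si_tol saturation-index complementarity tolerance, log10 units.
#' @param newton_tol convergence tolerance on the scaled residual norm.
#' @param max_assemblage_iter cap on add/remove cycles of the solid
#'   active-set loop.
#' @param max_newton_iter cap on Newton iterations per assemblage step.
#' @param mode `"fixed"` (default): nitrogen speciation is an input — the
#'   reduced NH3/NH4+ pool and the N2 pool are separately conserved, and
#'   all redox-active species are frozen out. `"h2"`: a hydrogen partial
#'   pressure is imposed as an open reservoir and N2 = NH3 equilibrates
#'   against it.
#' @param h2_partial_pressure imposed H2 pressure in bar (`mode = "h2"`).
#' @param reduced_p unfreeze the +3/+1 phosphorus species (sensitivity
#'   toggle, only meaningful with `mode = "h2"`).
#' @param active_include,active_exclude character vectors adjusting the
#'   default active species set.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(element_tol = 1e-9, si_tol = 1e-6,
                           newton_tol = 1e-12, max_assemblage_iter = 50L,
                           max_newton_iter = 200L,
                           mode = c("fixed", "h2"),
                           h2_partial_pressure = NULL,
                           reduced_p = FALSE,
                           active_include = NULL, active_exclude = NULL) {
  mode <- match.arg(mode)
  if (element_tol <= 0 || si_tol <= 0 || newton_tol <= 0)
    pc_stop("protocean_bad_options", "tolerances must be strictly positive")
  if (mode == "h2" && (is.null(h2_partial_pressure) || h2_partial_pressure <= 0))
    pc_stop("protocean_bad_options",
            "mode 'h2' requires a positive h2_partial_pressure")
  if (reduced_p && mode != "h2")
    pc_stop("protocean_bad_options",
            "reduced_p only meaningful in mode 'h2' (needs a redox handle)")
  structure(list(element_tol = element_tol, si_tol = si_tol,
                 newton_tol = newton_tol,
                 max_assemblage_iter = as.integer(max_assemblage_iter),
                 max_newton_iter = as.integer(max_newton_iter),
                 mode = mode, h2_partial_pressure = h2_partial_pressure,
                 reduced_p = reduced_p,
                 active_include = active_include,
                 active_exclude = active_exclude),
            class = "solver_options")
}

#' Bulk composition of a closed water + headspace system
#'
#' Element totals are moles per kilogram of solvent water. The reduced
#' nitrogen pool (NH3/NH4+) is tracked separately from inert N2 so the
#' fixed-speciation solver conserves each independently.
#'
#' @param element_totals named numeric vector over
#'   `H, O, Na, Cl, Mg, Ca, N, S, P` (missing entries are zero).
#' @param nitrogen_reduced moles of N (per kg water) in the reduced pool;
#'   must not exceed the N total.
#' @return object of class `system_composition`.
#' @export
system_composition <- function(element_totals, nitrogen_reduced = 0) {
  b <- setNames(numeric(length(PC_ELEMENTS)), PC_ELEMENTS)
  unknown <- setdiff(names(element_totals), PC_ELEMENTS)
  if (length(unknown))
    pc_stop("protocean_unknown_element", "unknown element(s): %s",
            paste(unknown, collapse = ", "))
  b[names(element_totals)] <- element_totals
  if (any(b < 0))
    pc_stop("protocean_bad_composition", "negative element total(s): %s",
            paste(names(b)[b < 0], collapse = ", "))
  if (nitrogen_reduced < -1e-15 || nitrogen_reduced > b["N"] + 1e-12)
    pc_stop("protocean_bad_composition",
            "nitrogen_reduced must lie in [0, N total]")
  if (b["O"] <= 0 || b["H"] <= 0)
    pc_stop("protocean_bad_composition",
            "composition must contain solvent water (H and O totals > 0)")
  # neutrality under the frozen oxidation states (inputs are neutral salts)
  q <- sum(PC_OXSTATE * b) - PC_OXSTATE["N"] * (b["N"] - nitrogen_reduced)
  if (abs(q) > 1e-9 * max(1, sum(abs(b))))
    pc_stop("protocean_bad_composition",
            "input composition carries net charge %.3e", q)
  structure(list(element_totals = b,
                 nitrogen_reduced = as.numeric(nitrogen_reduced),
                 temperature = PC_T, pressure = PC_P_TOTAL),
            class = "system_composition")
}

# default active species set (redox freezes; see vignette)
pc_default_active <- function(db, mode = "fixed", reduced_p = FALSE) {
  excl <- c("H(g)", "HNO3(aq)")
  if (!reduced_p)
    excl <- c(excl, "H3PO3(aq)", "H2PO3-", "HPO3-2", "H3PO2(aq)", "H2PO2-",
              "CaHPO3(s)")
  if (mode == "fixed")
    excl <- c(excl, "H2(aq)", "H2(g)", "O2(aq)", "O2(g)")
  setdiff(db$species$name, excl)
}

# Internal: assemble index structures for the Newton solver.
pc_solver_setup <- function(comp, db, opts) {
  b_el <- comp$element_totals
  active <- pc_default_active(db, opts$mode, opts$reduced_p)
  active <- union(setdiff(active, opts$active_exclude), opts$active_include)
  solvent <- db$species$name[db$species$phase_class == "solvent"]
  active <- setdiff(active, solvent)

  fixedN <- opts$mode == "fixed"
  n2_pool <- c("N2(aq)", "N2(g)")
  # component totals; in fixed mode N splits into reduced (Nr) / inert (Nn)
  if (fixedN) {
    comps <- c("H", "O", "Na", "Cl", "Mg", "Ca", "Nr", "Nn", "S", "P")
    b <- setNames(c(b_el[c("H", "O", "Na", "Cl", "Mg", "Ca")],
                    comp$nitrogen_reduced, b_el["N"] - comp$nitrogen_reduced,
                    b_el[c("S", "P")]), comps)
  } else {
    comps <- PC_ELEMENTS
    b <- b_el
  }
  # prune species of absent components (solvent elements always kept)
  dead <- setdiff(names(b)[b <= 0], c("H", "O"))
  amap <- function(sp) { # component column for one species
    f <- db$formula[sp, ]
    v <- setNames(numeric(length(comps)), comps)
    for (e in setdiff(PC_ELEMENTS, "N")) if (e %in% comps) v[e] <- f[e]
    if (f["N"] > 0) {
      if (!fixedN) v["N"] <- f["N"]
      else if (sp %in% n2_pool) v["Nn"] <- f["N"]
      else v["Nr"] <- f["N"]
    }
    v
  }
  A <- vapply(active, amap, numeric(length(comps)))
  rownames(A) <- comps
  keep <- colSums(A[dead, , drop = FALSE] != 0) == 0
  active <- active[keep]
  A <- A[, keep, drop = FALSE]
  live <- setdiff(comps, dead)
  A <- A[live, , drop = FALSE]
  b <- b[live]

  phase <- db$species[active, "phase_class"]
  z <- db$species[active, "charge"]
  dG <- db$species[active, "dGf"]
  dG_w <- db$species[solvent, "dGf"]
  # eliminate the O potential through the solvent equation
  # lambda_O = dGf(H2O) - 2 lambda_H, assuming solvent formula H2 O1
  Atil <- A
  if ("O" %in% live) {
    Atil["H", ] <- A["H", ] - 2 * A["O", ]
    gtil <- (dG - A["O", ] * dG_w) / PC_RT
    Atil <- Atil[setdiff(live, "O"), , drop = FALSE]
  } else gtil <- dG / PC_RT
  uc <- rownames(Atil)

  gas_on <- if (opts$mode == "h2") TRUE else ("Nn" %in% live && b["Nn"] > 0)
  list(comp = comp, db = db, opts = opts, active = active, A = A,
       Atil = Atil, gtil = gtil, b = b, live = live, uc = uc,
       is_aq = phase == "aqueous", is_gas = phase == "gas",
       is_solid = phase == "solid", z = z, dG = dG, dG_w = dG_w,
       solvent = solvent, gas_on = gas_on, fixedN = fixedN,
       h2aq_shift = if (all(c("H2(g)", "H2(aq)") %in% db$species$name))
         (db$species["H2(g)", "dGf"] - db$species["H2(aq)", "dGf"]) / PC_RT
       else NA_real_,
       qscale = max(1e-10, sum(b[intersect(c("Na", "Mg", "Ca", "Nr", "S", "P"),
                                           live)])),
       escale = pmax(b, 1e-10))
}

# Internal: residual + Jacobian at unknown vector u for a given assemblage.
# u = (theta[uc], [theta_q if h2], ln_nw, [ln_Ng if gas], n_solid[assemblage])
pc_residual <- function(u, st, solids) {
  opts <- st$opts
  nu <- length(st$uc); h2 <- opts$mode == "h2"
  i <- nu
  theta <- setNames(u[seq_len(nu)], st$uc)
  theta_q <- if (h2) u[(i <- i + 1)] else 0
  nw <- exp(u[(i <- i + 1)])
  Ng <- if (st$gas_on) exp(u[(i <- i + 1)]) else 0
  ns <- if (length(solids)) u[i + seq_along(solids)] else numeric(0)

  lna <- drop(crossprod(st$Atil, theta)) - st$gtil + st$z * theta_q
  lna <- pmin(lna, 200)                     # overflow guard far from solution
  W <- nw * PC_M_WATER
  m <- ifelse(st$is_aq, exp(lna), 0)
  p <- ifelse(st$is_gas, exp(lna), 0)
  n <- m * W + if (st$gas_on) Ng * p / PC_P_TOTAL else 0
  n[match(solids, st$active)] <- ns

  live <- st$live
  balance <- drop(st$A %*% n) - st$b
  if ("H" %in% live) balance["H"] <- balance["H"] + 2 * nw
  if ("O" %in% live) balance["O"] <- balance["O"] + nw
  rows <- setdiff(live, "H")
  R <- balance[rows] / st$escale[rows]
  R <- c(R, charge = sum(st$z * m) * W / st$qscale)
  if (st$gas_on) R <- c(R, closure = sum(p) - PC_P_TOTAL)
  if (h2) {
    # pin the imposed H2 fugacity: through the gas when a gas phase exists,
    # else through dissolved H2 at Henry-law equilibrium with that fugacity
    if (st$gas_on) {
      ih2 <- match("H2(g)", st$active)
      tgt <- log(opts$h2_partial_pressure)
    } else {
      ih2 <- match("H2(aq)", st$active)
      tgt <- log(opts$h2_partial_pressure) + st$h2aq_shift
    }
    R <- c(R, h2pin = unname(lna[ih2]) - tgt)
  }
  if (length(solids))
    R <- c(R, setNames(lna[match(solids, st$active)], solids))

  # Jacobian
  nun <- length(u)
  J <- matrix(0, length(R), nun, dimnames = list(names(R), NULL))
  naq <- m * W                                    # aqueous moles
  ngs <- if (st$gas_on) Ng * p / PC_P_TOTAL else rep(0, length(p))
  for (k in seq_len(nu)) {
    ak <- st$Atil[k, ]
    dn <- ak * (naq + ngs)
    dbal <- drop(st$A %*% dn)
    J[seq_along(rows), k] <- dbal[rows] / st$escale[rows]
    J["charge", k] <- sum(st$z * ak * naq) / st$qscale
    if (st$gas_on) J["closure", k] <- sum(ak * p)
    if (h2) J["h2pin", k] <- st$Atil[k, ih2]
    if (length(solids))
      J[solids, k] <- st$Atil[k, match(solids, st$active)]
  }
  if (h2) {
    kq <- nu + 1
    dn <- st$z * naq
    dbal <- drop(st$A %*% dn)
    J[seq_along(rows), kq] <- dbal[rows] / st$escale[rows]
    J["charge", kq] <- sum(st$z^2 * naq) / st$qscale
    if (length(solids))
      J[solids, kq] <- st$z[match(solids, st$active)]   # zero (solids neutral)
  }
  knw <- nu + h2 + 1
  dbal <- drop(st$A %*% naq)
  if ("H" %in% live) dbal["H"] <- dbal["H"] + 2 * nw
  if ("O" %in% live) dbal["O"] <- dbal["O"] + nw
  J[seq_along(rows), knw] <- dbal[rows] / st$escale[rows]
  J["charge", knw] <- sum(st$z * naq) / st$qscale
  if (st$gas_on) {
    kng <- knw + 1
    dbal <- drop(st$A %*% ngs)
    J[seq_along(rows), kng] <- dbal[rows] / st$escale[rows]
  }
  if (length(solids)) {
    for (s in seq_along(solids)) {
      ks <- knw + st$gas_on + s
      J[seq_along(rows), ks] <-
        st$A[rows, match(solids[s], st$active)] / st$escale[rows]
    }
  }
  list(R = R, J = J, theta = theta, theta_q = theta_q, nw = nw, Ng = Ng,
       m = m, p = p, lna = lna, n = n, W = W)
}

# Internal: damped Newton iteration; returns the final evaluation.
pc_newton <- function(u, st, solids) {
  opts <- st$opts
  ev <- pc_residual(u, st, solids)
  for (it in seq_len(opts$max_newton_iter)) {
    nrm <- max(abs(ev$R))
    if (!is.finite(nrm)) pc_stop("protocean_nonconvergence",
                                 "non-finite residual in Newton iteration")
    if (nrm < opts$newton_tol) return(c(ev, list(iterations = it, u = u)))
    ncore <- length(st$uc) + (opts$mode == "h2") + 1 + st$gas_on
    # a solid being driven hard negative marks an infeasible assemblage:
    # hand it back so the active-set loop can eject it
    if (length(solids)) {
      ns <- u[ncore + seq_along(solids)]
      if (any(ns < -4 * max(st$b)))
        return(c(ev, list(iterations = it, u = u)))
    }
    du <- NULL
    mu <- 0
    while (is.null(du)) {
      du <- tryCatch(
        if (mu == 0) solve(ev$J, -ev$R)
        else qr.solve(ev$J + diag(mu, nrow(ev$J)), -ev$R),
        error = function(e) NULL)
      if (is.null(du)) {
        mu <- if (mu == 0) 1e-12 else mu * 1e3
        if (mu > 1) pc_stop("protocean_nonconvergence",
                            "singular Newton system (assemblage {%s})",
                            paste(solids, collapse = ","))
      }
    }
    cap_t <- max(abs(du[seq_len(ncore)]))
    cap_s <- if (length(du) > ncore) max(abs(du[-seq_len(ncore)])) else 0
    smax <- 2 * max(st$b)   # bound solid-mole steps by the element inventory
    step <- min(1, if (cap_t > 15) 15 / cap_t else 1,
                if (cap_s > smax) smax / cap_s else 1)
    repeat {
      u_try <- u + step * du
      ev_try <- pc_residual(u_try, st, solids)
      if (all(is.finite(ev_try$R)) &&
          (max(abs(ev_try$R)) < nrm || step < 1e-6)) break
      step <- step / 2
    }
    # accept stagnation at rounding level (well inside every physical tol)
    if (max(abs(ev_try$R)) >= 0.99 * nrm && nrm < 1e-9)
      return(c(ev, list(iterations = it, u = u)))
    u <- u + step * du
    ev <- ev_try
  }
  pc_stop("protocean_nonconvergence",
          "Newton failed to converge (assemblage {%s}; max residual %.3e)",
          paste(solids, collapse = ","), max(abs(ev$R)))
}

# Internal: initial unknown vector from a crude mass-action partition.
pc_init <- function(st, perturb = 0) {
  opts <- st$opts
  b <- st$b; live <- st$live
  nw0 <- if ("O" %in% live) max(b["O"] - sum(b[setdiff(live, c("H", "O"))]), 1)
         else b["H"] / 2
  W0 <- nw0 * PC_M_WATER
  theta <- setNames(numeric(length(st$uc)), st$uc)
  gt <- function(sp) st$gtil[match(sp, st$active)]
  at <- function(sp) st$Atil[, match(sp, st$active)]
  theta["H"] <- if (opts$mode == "h2") log(opts$h2_partial_pressure) / 2
                else log(1e-7)
  theta_q <- if (opts$mode == "h2") log(1e-7) - theta["H"] else 0
  basis <- c(Na = "Na+", Cl = "Cl-", Mg = "Mg+2", Ca = "Ca+2", Nr = "NH4+",
             S = "HS-", P = "HPO4-2", N = "NH4+")
  for (e in intersect(names(basis), st$uc)) {
    sp <- basis[[e]]
    if (!sp %in% st$active) next
    be <- if (e == "N") b["N"] else b[e]
    lnm <- log(max(be, 1e-12) / W0 * 0.5)
    a <- at(sp)
    zq <- st$z[match(sp, st$active)] * theta_q
    theta[e] <- (lnm + gt(sp) - zq -
                   sum(a * theta) + a[e] * theta[e]) / a[e]
  }
  if ("Nn" %in% st$uc) {
    if (st$gas_on && "N2(g)" %in% st$active)
      theta["Nn"] <- (log(0.9) + gt("N2(g)")) / 2
    else if ("N2(aq)" %in% st$active)
      theta["Nn"] <- (log(max(b["Nn"], 1e-12) / W0) + gt("N2(aq)")) / 2
  }
  u <- theta + perturb * (0.5 * (-1)^seq_along(theta))
  if (opts$mode == "h2") u <- c(u, theta_q)
  u <- c(u, log(nw0))
  if (st$gas_on) u <- c(u, log(max(b[intersect("Nn", live)] / 2,
                                   if (opts$mode == "h2") b["N"] / 2 else 0,
                                   1e-8, na.rm = TRUE)))
  u
}

#' Solve for chemical equilibrium
#'
#' Finds the species distribution minimising total Gibbs energy subject to
#' element conservation, by damped Newton iteration on element potentials
#' (the dual law-of-mass-action formulation) wrapped in an active-set loop
#' that adds the most supersaturated solid and removes any solid driven to
#' negative moles, until the complementarity condition holds: every present
#' solid has saturation index 0, every absent one SI <= 0. Activities are
#' ideal: molality for solutes, partial pressure (bar) for gases, unity for
#' solids and solvent.
#'
#' @param comp a [system_composition()].
#' @param db a `thermo_db` (default: the shipped fixture).
#' @param opts a [solver_options()].
#' @return object of class `equilibrium_state`.
#' @export
solve_equilibrium <- function(comp, db = default_thermodb(),
                              opts = solver_options()) {
  st <- pc_solver_setup(comp, db, opts)
  if (length(st$active) == 0)
    pc_stop("protocean_infeasible", "no active species for this composition")
  for (e in st$live)
    if (st$b[e] > 0 && all(st$A[e, ] == 0) && !e %in% c("H", "O"))
      pc_stop("protocean_infeasible",
              "element %s has positive total but no active species", e)

  solids <- character(0)
  candidates <- st$active[st$is_solid]
  # Newton with deterministic perturbed restarts; warm start first, then
  # fresh initializations with the requested assemblage at zero moles
  try_newton <- function(u, solids) {
    ev <- tryCatch(pc_newton(u, st, solids), error = function(e) e)
    attempt <- 0
    while (inherits(ev, "error") && attempt < 3) {
      attempt <- attempt + 1
      u0 <- c(pc_init(st, perturb = attempt), rep(0, length(solids)))
      ev <- tryCatch(pc_newton(u0, st, solids), error = function(e) e)
    }
    if (inherits(ev, "error")) stop(ev)
    ev
  }
  ev <- tryCatch(try_newton(pc_init(st), character(0)), error = function(e) e)
  if (inherits(ev, "error") && st$opts$mode == "h2" && st$gas_on) {
    # the imposed H2/NH3 equilibrium can consume the N2 headspace entirely,
    # in which case no gas phase can sustain 1 bar: re-solve without one
    st$gas_on <- FALSE
    ev <- try_newton(pc_init(st), character(0))
  } else if (inherits(ev, "error")) stop(ev)
  u <- ev$u

  assemblage_iter <- 0L
  repeat {
    assemblage_iter <- assemblage_iter + 1L
    if (assemblage_iter > st$opts$max_assemblage_iter)
      pc_stop("protocean_nonconvergence",
              "assemblage loop exceeded %d iterations",
              st$opts$max_assemblage_iter)
    # complementarity check on candidates
    idx <- match(candidates, st$active)
    si <- (drop(crossprod(st$Atil[, idx, drop = FALSE], ev$theta)) -
             st$gtil[idx]) / log(10)
    names(si) <- candidates
    ns <- ev$n[match(solids, st$active)]
    neg <- solids[ns < -1e-15]
    if (length(neg)) {
      drop_s <- neg[which.min(ns[match(neg, solids)])]
      solids <- setdiff(solids, drop_s)
      ncore <- length(st$uc) + (st$opts$mode == "h2") + 1 + st$gas_on
      u <- c(ev$u[seq_len(ncore)], pmax(ev$n[match(solids, st$active)], 0))
      ev <- try_newton(u, solids)
      u <- ev$u
      next
    }
    absent <- setdiff(candidates, solids)
    over <- absent[si[absent] > st$opts$si_tol]
    if (length(over)) {
      # deterministic tie-break: largest SI, then lexicographic name
      add_s <- over[order(-si[over], over)][1]
      ncore <- length(st$uc) + (st$opts$mode == "h2") + 1 + st$gas_on
      ev_try <- tryCatch(try_newton(c(u, 0), c(solids, add_s)),
                         error = function(e) e)
      if (!inherits(ev_try, "error")) {
        solids <- c(solids, add_s)
      } else {
        # augmented assemblage numerically infeasible: the new solid is
        # displacing an existing one -- try swapping each out in turn
        swapped <- FALSE
        for (r in solids[order(solids)]) {
          sub <- c(setdiff(solids, r), add_s)
          ev_try <- tryCatch(
            try_newton(c(ev$u[seq_len(ncore)], rep(0, length(sub))), sub),
            error = function(e) e)
          if (!inherits(ev_try, "error")) {
            solids <- sub; swapped <- TRUE; break
          }
        }
        if (!swapped) stop(ev_try)
      }
      ev <- ev_try
      u <- ev$u
      next
    }
    break
  }
  pc_build_state(ev, st, solids, assemblage_iter)
}

# Internal: package a converged Newton evaluation as an equilibrium_state.
pc_build_state <- function(ev, st, solids, assemblage_iter) {
  W <- ev$W
  aq <- st$active[st$is_aq]
  gas <- st$active[st$is_gas]
  molal <- setNames(ev$m[st$is_aq], aq)
  pp <- setNames(ev$p[st$is_gas], gas)
  n_aq <- molal * W
  n_gas <- if (st$gas_on) setNames(ev$Ng * pp / PC_P_TOTAL, gas) else
    setNames(rep(0, length(gas)), gas)
  n_sol <- setNames(ev$n[match(solids, st$active)], solids)
  species_moles <- c(setNames(ev$nw, st$solvent), n_aq, n_gas, n_sol)

  idx <- match(st$active[st$is_solid], st$active)
  si <- (drop(crossprod(st$Atil[, idx, drop = FALSE], ev$theta)) -
           st$gtil[idx]) / log(10)
  names(si) <- st$active[st$is_solid]

  # reconstruct full element potentials (kJ/mol) incl. the eliminated O
  lambda <- ev$theta * PC_RT
  if ("O" %in% st$live)
    lambda <- c(lambda, O = unname(st$dG_w - 2 * lambda["H"]))
  totG <- sum(n_aq * (st$dG[st$is_aq] + PC_RT * log(pmax(molal, 1e-300)))) +
    sum(n_gas * (st$dG[st$is_gas] + PC_RT * log(pmax(pp, 1e-300)))) +
    sum(n_sol * st$dG[match(solids, st$active)]) +
    ev$nw * st$dG_w

  structure(list(
    species_moles = species_moles,
    molalities = molal,
    solid_assemblage = names(n_sol)[n_sol > 0],
    pH = -log10(molal[["H+"]]),
    gas_partial_pressures = if (st$gas_on) pp else setNames(numeric(0), NULL),
    gas_moles_total = if (st$gas_on) ev$Ng else 0,
    water_moles = unname(ev$nw),
    total_G = unname(totG),
    saturation_indices = si,
    lambda = lambda, theta_q = ev$theta_q,
    composition = st$comp, mode = st$opts$mode,
    h2_partial_pressure = st$opts$h2_partial_pressure,
    active_species = st$active,
    newton_iterations = ev$iterations,
    assemblage_iterations = assemblage_iter,
    max_residual = max(abs(ev$R))), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state>\n")
  cat(sprintf("  pH %.4f | water %.4f mol | total G %.6g kJ\n",
              x$pH, x$water_moles, x$total_G))
  cat("  solids:", if (length(x$solid_assemblage))
    paste(x$solid_assemblage, collapse = ", ") else "(none)", "\n")
  if (length(x$gas_partial_pressures)) {
    gp <- x$gas_partial_pressures[x$gas_partial_pressures > 1e-15]
    cat("  gas (bar):", paste(sprintf("%s=%.3g", names(gp), gp),
                              collapse = ", "), "\n")
  }
  top <- sort(x$molalities, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(8, sum(top > 0)))]
  cat("  major solutes (mol/kg):",
      paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Saturation index of a solid
#'
#' `SI = log10(IAP / Ksp)` for the solid's dissolution reaction, computed
#' from the state's dissolved-ion activities via an expansion of the solid
#' into basis species (water and solids contribute activity one). Zero (to
#' tolerance) for solids in the equilibrium assemblage, negative for
#' undersaturated ones.
#'
#' @param state an `equilibrium_state`; @param solid a solid species name;
#' @param db the `thermo_db` used to solve the state.
#' @return SI in log10 units.
#' @export
saturation_index <- function(state, solid, db = default_thermodb()) {
  if (!solid %in% db$species$name ||
      db$species[solid, "phase_class"] != "solid")
    pc_stop("protocean_not_a_solid", "'%s' is not a solid in the database",
            solid)
  expand <- pc_basis_expansion(db, solid, mode = state$mode)
  loga <- pc_log_activities(state)
  rxn <- reaction(setNames(c(-1, expand$coef), c(solid, expand$basis)))
  lk <- reaction_logK(db, rxn)
  ions <- expand$basis[abs(expand$coef) > 1e-12]
  if (!all(ions %in% names(loga))) return(-Inf)
  sum(expand$coef[match(ions, expand$basis)] * loga[ions]) - lk
}

# Internal: log10 activities of water (0), aqueous solutes and gases.
pc_log_activities <- function(state) {
  aq <- log10(state$molalities)
  gp <- if (length(state$gas_partial_pressures))
    log10(state$gas_partial_pressures) else setNames(numeric(0), NULL)
  solv <- setNames(0, names(state$species_moles)[1])
  c(solv, aq, gp)
}

# Internal: expand a species into the canonical basis set by solving the
# element+charge linear system; used by saturation_index and verify_state.
pc_basis_expansion <- function(db, species, mode = "fixed") {
  basis <- c("H2O(l)", "H+", "Na+", "Cl-", "Mg+2", "Ca+2", "NH4+",
             if (mode == "fixed") "N2(g)" else "H2(g)", "HS-", "PO4-3")
  basis <- intersect(basis, db$species$name)
  n2 <- c("N2(aq)", "N2(g)")
  colfun <- function(sp) {
    f <- db$formula[sp, ]
    v <- c(f, setNames(0, "Nn"))
    if (mode == "fixed" && sp %in% n2) { v["Nn"] <- f["N"]; v["N"] <- 0 }
    c(v, charge = db$species[sp, "charge"])
  }
  B <- vapply(basis, colfun, numeric(length(PC_ELEMENTS) + 2))
  target <- colfun(species)
  fit <- qr(B)
  coef <- qr.coef(fit, target)
  coef[is.na(coef)] <- 0
  if (max(abs(B %*% coef - target)) > 1e-9)
    pc_stop("protocean_unbalanced_reaction",
            "species '%s' cannot be expanded in the basis set", species)
  list(basis = basis, coef = coef)
}

#' Equilibrium ammonia partial pressure over an N2/H2 atmosphere
#'
#' Uses the gas-phase equilibrium `1/2 N2 + 3/2 H2 = NH3`, whose constant
#' comes from the database: ammonia formation is controlled by the hydrogen
#' fugacity. Monotone non-decreasing in both arguments.
#'
#' @param pN2,pH2 partial pressures in bar (vectorised).
#' @param db a `thermo_db`.
#' @return equilibrium NH3 partial pressure, bar.
#' @export
ammonia_redox_equilibrium <- function(pN2, pH2, db = default_thermodb()) {
  if (any(pN2 < 0) || any(pH2 < 0))
    pc_stop("protocean_bad_composition", "partial pressures must be >= 0")
  lk <- reaction_logK(db, reaction(c("N2(g)" = -0.5, "H2(g)" = -1.5,
                                     "NH3(g)" = 1)))
  10^lk * sqrt(pN2) * pH2^1.5
}

#' Verify an equilibrium state against its governing equations
#'
#' Recomputes, independently of the solver internals, (i) element-balance
#' residuals from the reported species moles, (ii) the aqueous charge
#' residual, (iii) a mass-action residual `log10 Q - log10 K` for every
#' active species expanded into basis species, and (iv) the solid
#' complementarity conditions. An empty (all-`ok`) report certifies the
#' state.
#'
#' @param state an `equilibrium_state`; @param comp the composition it
#'   solved; @param db the database; @param opts tolerances.
#' @return data.frame `check`, `item`, `residual`, `tol`, `ok`, with
#'   attribute `ok` summarising the whole report.
#' @export
verify_state <- function(state, comp, db = default_thermodb(),
                         opts = solver_options()) {
  rep <- list()
  add <- function(check, item, residual, tol, ok = abs(residual) <= tol)
    rep[[length(rep) + 1L]] <<- data.frame(check = check, item = item,
                                           residual = residual, tol = tol,
                                           ok = ok)
  n <- state$species_moles
  A <- db$formula[names(n), , drop = FALSE]
  got <- drop(n %*% A)
  b <- comp$element_totals
  for (e in PC_ELEMENTS) {
    if (b[e] <= 0 && got[e] <= 0) next
    r <- (got[e] - b[e]) / max(b[e], 1e-10)
    if (e == "H" && state$mode == "h2")
      add("h2-reservoir-flux", e, r, Inf, TRUE)
    else add("element-balance", e, r, opts$element_tol)
  }
  zch <- sum(db$species[names(state$molalities), "charge"] * state$molalities)
  add("charge-balance", "aqueous", zch, 1e-12)   # mol per kg water
  # mass action for every dissolved/gas species vs. the basis set
  loga <- pc_log_activities(state)
  basis_all <- unique(c("H2O(l)", "H+", "Na+", "Cl-", "Mg+2", "Ca+2", "NH4+",
                        "N2(g)", "H2(g)", "HS-", "PO4-3"))
  for (sp in c(names(state$molalities), names(state$gas_partial_pressures))) {
    if (sp %in% basis_all) next
    ex <- tryCatch(pc_basis_expansion(db, sp, state$mode),
                   error = function(e) NULL)
    if (is.null(ex)) next
    lk <- reaction_logK(db, reaction(setNames(c(-1, ex$coef),
                                              c(sp, ex$basis))))
    ions <- ex$basis[abs(ex$coef) > 1e-12]
    if (!all(ions %in% names(loga))) next
    r <- loga[[sp]] - (sum(ex$coef[match(ions, ex$basis)] * loga[ions]) - lk)
    add("mass-action", sp, r, opts$si_tol)
  }
  cand <- db$species$name[db$species$phase_class == "solid"]
  cand <- intersect(cand, state$active_species)
  for (s in cand) {
    si <- saturation_index(state, s, db)
    if (s %in% state$solid_assemblage)
      add("complementarity-present", s, si, opts$si_tol)
    else add("complementarity-absent", s, min(si, 0), opts$si_tol,
             ok = si <= opts$si_tol)
  }
  out <- do.call(rbind, rep)
  attr(out, "ok") <- all(out$ok)
  out
}
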