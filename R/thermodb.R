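#' Parse an element-count formula string
#'
#' Formulas are written as whitespace-separated element-count tokens, e.g.
#' `"Mg1 N1 H16 P1 O10"` for struvite with its six waters of hydration.
#'
#' @param x a single formula string.
#' @return named integer vector over [PC_ELEMENTS] (zero for absent elements).
#' @keywords internal
parse_formula <- function(x) {
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  if (length(tokens) == 0L || !nzchar(tokens[1]))
    pc_stop("protocean_bad_formula", "empty formula")
  out <- setNames(numeric(length(PC_ELEMENTS)), PC_ELEMENTS)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([A-Z][a-z]?)([0-9]+)$", tok))[[1]]
    if (length(m) != 3L)
      pc_stop("protocean_bad_formula", "malformed formula token '%s'", tok)
    el <- m[2]
    if (!el %in% PC_ELEMENTS)
      pc_stop("protocean_unknown_element",
              "unknown element symbol '%s' in formula '%s'", el, x)
    out[el] <- out[el] + as.numeric(m[3])
  }
  out
}

#' Load a thermodynamic database from a TSV file
#'
#' The file format is tab-separated text with comment lines starting with
#' `#` (the first of which carries the database version string) and columns
#' `name`, `formula`, `charge`, `phase_class`, `dGf_kJ_per_mol`, `source`.
#' Standard-state Gibbs energies of formation are at 298.15 K / 1 bar;
#' activity conventions are molality (aqueous), partial pressure in bar
#' (gas) and unity (solids, solvent).
#'
#' @param path path to the TSV file.
#' @return an object of class `thermo_db`: a list with `species`
#'   (data.frame), `formula` (species x element matrix), `elements`,
#'   `version`, `reference_temperature`, `reference_pressure`.
#' @export
load_thermodb <- function(path) {
  if (!file.exists(path))
    pc_stop("protocean_io_error", "database file '%s' does not exist", path)
  lines <- readLines(path)
  version <- sub("^#\\s*", "", lines[startsWith(lines, "#")][1])
  if (is.na(version)) version <- "unversioned"
  tab <- read.delim(text = lines[!startsWith(lines, "#")],
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "formula", "charge", "phase_class", "dGf_kJ_per_mol", "source")
  if (!all(need %in% names(tab)))
    pc_stop("protocean_bad_schema", "missing column(s): %s",
            paste(setdiff(need, names(tab)), collapse = ", "))
  if (anyDuplicated(tab$name))
    pc_stop("protocean_duplicate_species", "duplicate species name(s): %s",
            paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  dGf <- suppressWarnings(as.numeric(tab$dGf_kJ_per_mol))
  if (anyNA(dGf))
    pc_stop("protocean_bad_dGf", "missing or non-numeric dGf for: %s",
            paste(tab$name[is.na(dGf)], collapse = ", "))
  if (!all(tab$phase_class %in% c("aqueous", "gas", "solid", "solvent")))
    pc_stop("protocean_bad_schema", "unknown phase_class value(s): %s",
            paste(setdiff(tab$phase_class,
                          c("aqueous", "gas", "solid", "solvent")), collapse = ", "))
  if (sum(tab$phase_class == "solvent") != 1L)
    pc_stop("protocean_no_solvent",
            "database must contain exactly one solvent species")
  fm <- t(vapply(tab$formula, parse_formula, numeric(length(PC_ELEMENTS))))
  rownames(fm) <- tab$name
  db <- structure(list(
    species = data.frame(name = tab$name, charge = as.numeric(tab$charge),
                         phase_class = tab$phase_class, dGf = dGf,
                         source = tab$source, row.names = tab$name,
                         stringsAsFactors = FALSE),
    formula = fm, elements = PC_ELEMENTS, version = version,
    reference_temperature = PC_T, reference_pressure = PC_P_TOTAL),
    class = "thermo_db")
  db
}

#' The pinned thermodynamic database shipped with the package
#'
#' Loads (and caches) `inst/extdata/thermo_db.tsv`, a self-consistent 25 C
#' compilation covering the full species inventory of the model: the
#' aqueous phosphate ladder, ammonia/ammonium, sulfide, the major seawater
#' ions, seven gases, thirteen phosphate solids and five oxides. Solids are
#' pinned to literature solubility products (see the `source` column).
#'
#' @return a `thermo_db` object.
#' @export
default_thermodb <- function() {
  if (is.null(.pc_env$db)) {
    path <- system.file("extdata", "thermo_db.tsv", package = "protocean")
    .pc_env$db <- load_thermodb(path)
  }
  .pc_env$db
}

#' @export
print.thermo_db <- function(x, ...) {
  cat("<thermo_db> ", x$version, "\n", sep = "")
  cat("  ", nrow(x$species), " species (",
      paste(names(table(x$species$phase_class)),
            table(x$species$phase_class), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# species every usable database must contain (the model ocean inventory)
pc_required_species <- function() {
  c("H2O(l)", "H+", "OH-", "H3PO4(aq)", "H2PO4-", "HPO4-2", "PO4-3",
    "NH3(aq)", "NH4+", "H2S(aq)", "HS-", "Mg+2", "Ca+2", "Na+", "Cl-",
    "N2(g)", "H2(g)", "NH3(g)", "H2O(g)",
    "Struvite", "Hydroxyapatite", "Monetite", "Brushite", "Whitlockite",
    "Farringtonite", "Ca(H2PO4)2(s)", "Ca(H2PO4)2:H2O(s)", "Ca2P2O7(s)",
    "Mg2P2O7(s)", "CaHPO3(s)", "NaH2PO4(s)", "Na2HPO4(s)",
    "Lime", "Portlandite", "CaMgO2(s)", "Periclase", "Brucite")
}

#' Validate a thermodynamic database
#'
#' Checks the type invariants (unique names, unique composition triples,
#' charge conventions per phase, single solvent) and that every species of
#' the model inventory is present. This is a reporting operation: it never
#' throws; an empty report means the database is valid.
#'
#' @param db a `thermo_db`.
#' @return data.frame with columns `species`, `rule`, `message`; zero rows
#'   if the database passes.
#' @export
validate_thermodb <- function(db) {
  f <- list()
  add <- function(species, rule, message)
    f[[length(f) + 1L]] <<- data.frame(species = species, rule = rule,
                                       message = message)
  sp <- db$species
  dup <- sp$name[duplicated(sp$name)]
  for (d in dup) add(d, "unique-name", "duplicate species name")
  key <- paste(apply(db$formula, 1, paste, collapse = ","),
               sp$charge, sp$phase_class)
  for (d in sp$name[duplicated(key) | duplicated(key, fromLast = TRUE)])
    add(d, "unique-composition",
        "duplicate (formula, charge, phase_class) triple")
  for (i in seq_len(nrow(sp))) {
    if (sp$phase_class[i] %in% c("gas", "solid", "solvent") && sp$charge[i] != 0)
      add(sp$name[i], "charge-convention",
          "gas/solid/solvent species must have charge 0")
    if (sum(db$formula[i, ]) <= 0)
      add(sp$name[i], "non-empty-formula", "formula has no atoms")
  }
  # charge consistent with frozen oxidation states for the default-active set
  act <- pc_default_active(db)
  for (nm in act) {
    ox <- PC_OXSTATE
    if (nm %in% c("N2(aq)", "N2(g)")) ox["N"] <- 0  # inert dinitrogen pool
    zz <- sum(ox * db$formula[nm, ])
    if (abs(zz - sp[nm, "charge"]) > 1e-9)
      add(nm, "charge-oxstate",
          "charge inconsistent with formula convention (frozen oxidation states)")
  }
  if (sum(sp$phase_class == "solvent") != 1)
    add("(database)", "single-solvent", "exactly one solvent species required")
  for (nm in setdiff(pc_required_species(), sp$name))
    add(nm, "required-species", "required species absent")
  if (length(f) == 0)
    data.frame(species = character(), rule = character(), message = character())
  else do.call(rbind, f)
}

#' Construct a reaction
#'
#' @param stoichiometry named numeric vector of species coefficients,
#'   products positive, reactants negative.
#' @return an object of class `reaction`.
#' @export
reaction <- function(stoichiometry) {
  if (is.null(names(stoichiometry)) && length(stoichiometry) > 0)
    pc_stop("protocean_bad_reaction", "stoichiometry must be a named vector")
  structure(list(stoichiometry = stoichiometry[stoichiometry != 0]),
            class = "reaction")
}

#' Element and charge imbalance of a reaction
#'
#' @param db a `thermo_db`; @param rxn a `reaction`.
#' @return named vector of net element counts plus `charge` (all zero for a
#'   balanced reaction).
#' @export
reaction_balance <- function(db, rxn) {
  s <- rxn$stoichiometry
  unknown <- setdiff(names(s), db$species$name)
  if (length(unknown))
    pc_stop("protocean_unknown_species", "unknown species: %s",
            paste(unknown, collapse = ", "))
  if (length(s) == 0)
    return(c(setNames(numeric(length(PC_ELEMENTS)), PC_ELEMENTS), charge = 0))
  el <- drop(s %*% db$formula[names(s), , drop = FALSE])
  c(el, charge = sum(s * db$species[names(s), "charge"]))
}

#' log10 equilibrium constant of a balanced reaction
#'
#' `logK = -dG_rxn / (RT ln 10)` with `dG_rxn` the exact linear combination
#' of the member standard Gibbs energies of formation. Reversing a reaction
#' negates logK; summing reactions sums logK.
#'
#' @param db a `thermo_db`; @param rxn a `reaction`.
#' @param check if `TRUE` (default) element/charge balance is verified first.
#' @return log10 K (dimensionless).
#' @export
reaction_logK <- function(db, rxn, check = TRUE) {
  if (check) {
    bal <- reaction_balance(db, rxn)
    if (any(abs(bal) > 1e-9))
      pc_stop("protocean_unbalanced_reaction",
              "reaction not balanced: %s",
              paste(sprintf("%s=%+g", names(bal)[abs(bal) > 1e-9],
                            bal[abs(bal) > 1e-9]), collapse = ", "))
  }
  s <- rxn$stoichiometry
  if (length(s) == 0) return(0)
  dG <- sum(s * db$species[names(s), "dGf"])
  -dG / PC_RTLN10
}

#' The struvite formation reaction
#'
#' `Mg+2 + NH4+ + PO4-3 + 6 H2O = MgNH4PO4.6H2O`; its reverse (with unit
#' water activity) defines the solubility product.
#'
#' @return a `reaction`.
#' @export
struvite_formation <- function() {
  reaction(c("Mg+2" = -1, "NH4+" = -1, "PO4-3" = -1, "H2O(l)" = -6,
             "Struvite" = 1))
}
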