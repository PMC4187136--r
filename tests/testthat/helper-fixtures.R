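# shared fixtures: the pinned database and a few scenario shorthands

pc_db <- function() default_thermodb()

# kg of water for the unit basis used throughout the tests
PC_KGW <- 1 / 18.0153e-3

# composition of pure water on a 1 kg basis
comp_pure_water <- function() {
  system_composition(c(H = 2 * PC_KGW, O = PC_KGW))
}

# two-species phosphate buffer: 0.008 NaH2PO4 + 0.002 Na2HPO4 per kg
comp_phosphate_buffer <- function() {
  system_composition(c(H = 2 * PC_KGW + 2 * 0.008 + 1 * 0.002,
                       O = PC_KGW + 4 * 0.01,
                       Na = 0.008 + 2 * 0.002, P = 0.01))
}

# early-ocean scenario at a given Mg/Ca ratio and ammonium load
scenario_mgca <- function(ratio, ammonium = NULL, phosphate = 1e-5) {
  s <- default_early_ocean()
  s$mg_ca_ratio_override <- ratio
  s$total_phosphate <- phosphate
  s$ammonium_molality <- ammonium
  s
}

# write a tiny thermo database TSV from a data.frame of rows
write_mini_db <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "name\tformula\tcharge\tphase_class\tdGf_kJ_per_mol\tsource"
  lines <- c("# mini-db v0", header,
             apply(rows, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  path
}
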