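---
title: "Modelling struvite stability in a sulfide-buffered early ocean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling struvite stability in a sulfide-buffered early ocean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protocean)
```

## The question and the model

Whether struvite (MgNH4PO4·6H2O) could precipitate from an early ocean is
decided by equilibrium competition: calcium phosphates — hydroxyapatite
above all — are thermodynamically preferred hosts for dissolved phosphate,
and magnesium phosphate (farringtonite) takes over at high phosphate
loads. `protocean` models a closed water + headspace system in the
Na–Cl–Mg–Ca–N–S–P space at 298.15 K and 1 bar and asks, for a given water
chemistry, which phosphate solids coexist with the solution at the
minimum-Gibbs-energy state.

The equilibrium conditions are the usual trio: element conservation,
mass-action consistency for every reaction among aqueous and gas species,
and complementarity for solids (a candidate solid either is present with
saturation index zero, or absent and undersaturated). Activities are
ideal throughout: molality for solutes, partial pressure (bar) for gases,
unity for solids and for water. The model deliberately applies no
activity-coefficient correction — the sulfide buffer drives ionic strength
far beyond the validity of Davies-type corrections anyway, and all results
should be read as ideal-solution statements. Kinetics, metastability,
temperature dependence and sorption are out of scope.

## Thermodynamic data

Every constant comes from one pinned TSV
(`system.file("extdata", "thermo_db.tsv", package = "protocean")`), 49
species with a provenance column per row. Aqueous ions and gases carry
CODATA/NBS standard Gibbs energies of formation; solids are
*back-computed* from literature solubility products using those same ion
values, so each cited pKsp is reproduced exactly by construction:

```{r anchors}
db <- default_thermodb()
reaction_logK(db, reaction(c("H2O(l)" = -1, "H+" = 1, "OH-" = 1)))   # -pKw
reaction_logK(db, reaction(c("Struvite" = -1, "Mg+2" = 1, "NH4+" = 1,
                             "PO4-3" = 1, "H2O(l)" = 6)))            # -pKsp
```

Anchor choices that matter and why:

* **struvite pKsp 12.60** — the classical 25 °C determination; reported
  values span roughly 12.6–13.3, and the choice propagates linearly into
  every ammonium threshold.
* **hydroxyapatite pKsp 58.60** — within the published 57.5–59.6 spread;
  it controls the Mg/Ca ratio at which apatite releases phosphate to
  struvite (sensitivity ∝ Ksp^(1/5)).
* **farringtonite pKsp 24.70** — reported values range ~23.3–25.2; the
  middle of that envelope keeps the magnesium-phosphate competition
  regime consistent with the rest of the dataset. Because no primary
  25 °C measurement is definitive, this is the most uncertain constant in
  the database; its provenance note is in the TSV itself.

Reduced-phosphorus species (H3PO2/H3PO3 and their anions, CaHPO3) and
monatomic H gas are shipped for completeness but excluded from the
default active set: under the frozen-redox scheme below they cannot hold
mass, and unfrozen they are numerically destabilising trace channels. A
`reduced_p` toggle re-activates them in the hydrogen-coupled mode.

## Redox freezes and the two nitrogen modes

The model ocean is poised by construction, not by a free redox variable:

* **Sulfur** exists only as H2S/HS⁻ (the buffer); no sulfate chemistry.
* **Phosphorus** is +5 unless `reduced_p = TRUE`.
* **Nitrogen** has two modes. In the default *fixed-speciation* mode the
  reduced pool (NH3/NH4⁺) and the N2 pool are independently conserved
  components — this is the natural reading of a sweep that converts N2 to
  NH3 in prescribed proportions, and it keeps ammonia from draining into
  N2 at equilibrium. In the *h2-coupled* mode a hydrogen partial pressure
  is imposed as an open reservoir and ½N2 + 3/2H2 ⇌ NH3 equilibrates
  freely; ammonium then rises as pH2^(3/2) until the nitrogen inventory
  is exhausted. (The NH3-formation stoichiometry is reconstructed from
  the statement that ammonia is controlled by hydrogen fugacity; it is
  the only chemically balanced candidate.)

A technical consequence worth recording: with all oxidation states
frozen, a species is admitted to the active set only if its charge equals
the sum of its elements' frozen oxidation states. That rule makes input
charge balance a linear combination of the element balances, so the
solver can enforce charge balance in place of the hydrogen balance and
recover hydrogen conservation exactly. In h2-coupled mode the system is
open to H2, so the hydrogen total is an output; `verify_state()` reports
the implied H2 flux instead of flagging it as a violation.

## The solver

`solve_equilibrium()` runs damped Newton iteration on element potentials
(log-scale chemical potentials per component), with the solvent's oxygen
potential eliminated through the unit-water-activity condition, a closure
equation for the 1-bar headspace, and one algebraic condition (SI = 0)
per present solid. The active-set loop adds the most supersaturated
absent solid (ties broken by larger SI, then lexicographic name), removes
any solid driven to negative moles, and — when an augmented assemblage is
numerically infeasible because the newcomer displaces an incumbent
(struvite displacing farringtonite at high ammonium is the canonical
case) — swaps rather than grows. The headspace itself can vanish: if the
equilibrium partial pressures cannot sum to 1 bar (e.g. the N2 inventory
is consumed into ammonium under imposed H2), the gas phase is dropped and
the H2 constraint is applied through dissolved H2 at Henry-law
equilibrium.

Numerical choices: Newton steps capped at 15 log units (and solid-mole
steps at twice the largest element inventory), backtracking line search,
convergence at a scaled residual of 1e-12 with stagnation acceptance at
1e-9, at most 200 Newton iterations per assemblage and 50 assemblage
moves, deterministic perturbed restarts on failure. Elements with zero
totals are pruned together with their species before solving. There is no
random number generator anywhere in the pipeline, so every result is
bit-reproducible.

Direct Gibbs minimisation exists only as the independent test oracle, on
a reduced water/Mg/NH4/phosphate/struvite system. One subtlety uncovered
there is worth preserving: with molality-scale ideality and unit water
activity, the naive total `sum(n * mu)` is *not* a variational potential
(it violates Gibbs–Duhem); the consistent functional carries an extra
−RT per solute mole, and with that term the brute-force grid minimum
agrees with the mass-action solution to grid resolution.

## The scenario generator

`default_early_ocean()` encodes the study conditions: 1 kg of water (the
desk-scale normalisation; scale invariance is a tested property, so
results are identical at any mass), N2 in the atmosphere:ocean proportion
85,000 : 5.56e7, seawater Na/Mg/Ca pinned at 0.4686/0.05282/0.01028
mol/kg (standard mean-seawater molalities; the source text names only
"seawater salinity"), Cl⁻ as the balancing anion, phosphate as a 4:1
NaH2PO4:Na2HPO4 mix, and the H2S/Na2S buffer. Manipulations mirror the
study design: `mg_ca_ratio_override` re-partitions Mg+Ca at fixed sum
(a `mg_ca_fix_mg` flag provides the fix-Mg alternative for sensitivity
checks), `ammonia_fraction` converts N2 to NH3 at fixed total N, and
`ammonium_molality` supplies reduced nitrogen beyond the atmospheric
inventory — necessary because the interesting ammonium range extends far
above the total N the N2 inventory could provide.

Two buffer details are deliberate:

* The 4:1 phosphate split is kept as a *composition recipe* even though,
  as a pH-setting buffer, 4:1 NaH2PO4:Na2HPO4 would sit near pH 6.6, not
  in the reported 7.6–7.9 band. The sulfide buffer controls pH; the salt
  ratio only fixes which sodium/phosphate moles enter the water. The
  apparent tension between the salt ratio and the stated operating pH of
  7.8 is resolved in exactly this way — band and target authoritative,
  recipe nominal.
* "Excess" sulfide is sized per composition: `calibrate_buffer()` sets
  the sulfide total to 40× the reduced-N + phosphate acid/base load
  (floor 1 mol/kg) and tunes the H2S:Na2S split by secant iteration
  against full equilibrium solves until the solved pH hits the target
  (default 7.8) within 0.005. Na2S is a strong base here — the ladder has
  no S²⁻, so each mole arrives as HS⁻ + OH⁻ — which is why the H2S
  fraction of a pH-7.8 buffer is 0.567 rather than the naive
  Henderson–Hasselbalch 0.135. Sweeps and threshold searches recalibrate
  at every evaluated point, so the whole map sits inside the pH band. A
  single buffer sized for the largest swept ammonium would push hundreds
  of molal Na⁺ into every cell and precipitate sodium phosphates as an
  artifact; proportional sizing avoids that. (At bisection bracket tops
  near 10 mol/kg ammonium the buffer is still enormous — an ideal-model
  abstraction to hold pH, not a claim about a plausible ocean.)

What the generator does *not* emulate: K, carbonate, borate and sulfate
chemistry, activity coefficients, temperature structure, kinetic
inhibition. Tests passing on these scenarios certify the equilibrium
arithmetic under the stated idealisations, not the realism of the input
ocean.

## Phase maps and thresholds

`sweep_phasemap()` solves one equilibrium per grid cell (40×40 is the
default axis resolution; the shipped tests use coarser grids, 5×5, to
keep the suite fast — cell independence is itself a tested property) and
labels each cell with its phosphate-bearing assemblage. `find_threshold()`
bisects a single parameter in log space to relative width 1e-3
(~14 solves per boundary). Struvite "presence" means more than 1e-12 mol
per kg water, a pure numerical floor.

The acceptance script (`scripts/acceptance.R`, ~2 min) recomputes three
boundaries: the Mg/Ca ratio above which struvite is the sole phosphate
solid, the ammonium threshold at Mg/Ca 10,000 and 1e-5 mol/kg phosphate,
and the ammonium floor over phosphate totals in [1e-4, 1e-1] mol/kg.
Given the spread of published solubility products (struvite alone spans
half a log unit), agreement with independently published threshold values
should be judged at the factor-of-two level, and that is the band the
test suite records. One structural observation from this model: at the
top of the phosphate grid dissolved magnesium is nearly exhausted by
farringtonite (3 × its moles approach the 0.063 mol/kg Mg inventory),
which pulls the per-phosphate ammonium threshold below what a
farringtonite-buffered scaling would suggest — the floor of that curve is
therefore sensitive to how far the phosphate axis extends.

## Known limitations

* Ideal activities: at sulfide loads of several mol/kg the true ionic
  strength is far beyond any dilute theory; all stability fields are
  conditional on the ideal-solution convention.
* The farringtonite constant is the least certain anchor; shifting it
  across its literature envelope moves the high-phosphate competition
  boundary by roughly a factor of two in ammonium.
* Fixed 298.15 K / 1 bar only; no temperature derivatives are stored.
* The h2-coupled mode treats O2 as a spectator (it underflows to zero
  under any H2-bearing condition), so the model cannot describe oxidising
  atmospheres.
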