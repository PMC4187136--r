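# protocean

Equilibrium phosphate-mineral chemistry of a model early ocean.

Struvite (MgNH4PO4·6H2O) has been proposed as a prebiotic phosphorylating
mineral, but whether it could ever have precipitated from early-ocean
seawater is a thermodynamic question: struvite competes for phosphate with
the calcium phosphates (hydroxyapatite, monetite, brushite, whitlockite)
and, at high phosphate loads, with farringtonite (Mg3(PO4)2). `protocean`
answers that question by chemical-equilibrium modelling: it computes the
full aqueous/gas/solid speciation of a closed Na–Cl–Mg–Ca–N–S–P water mass
at 298.15 K and 1 bar, and maps where in (Mg/Ca ratio, ammonium, total
phosphate, hydrogen fugacity) space struvite is stable. It is written for
geochemists and origins-of-life researchers who want these stability
fields computed reproducibly from a pinned, inspectable thermodynamic
database rather than from proprietary black-box data.

## The model

The solver finds the species distribution minimising total Gibbs energy
subject to element conservation — equivalently, the state satisfying every
mass-action law plus solid complementarity. For each aqueous/gas reaction

    log10 K = −ΔG°rxn / (RT ln 10),  ΔG°rxn = Σ νi ΔG°f,i

and for each candidate solid the saturation index

    SI = log10(IAP / Ksp)

must be 0 for solids in the assemblage and ≤ 0 for absent ones.
Activities are ideal (molality for solutes, partial pressure in bar for
gases, unity for solids and solvent); no activity-coefficient model is
applied. Numerically the package uses damped Newton iteration on element
potentials (the dual law-of-mass-action formulation, the classic
geochemical-speciation architecture) wrapped in an active-set loop over
the 18 candidate solids. Nitrogen redox is frozen by default (NH4+/NH3
totals are inputs, N2 is an inert pool, matching a 0–100 % NH3 sweep); an
alternative mode equilibrates N2 + H2 ⇌ NH3 against an imposed hydrogen
partial pressure. Sulfur is locked to sulfide (the H2S/Na2S pH buffer) and
phosphorus to +5, with reduced-P species shipped but inactive.

The scenario generator reproduces a model ocean: 1 kg of water carrying
the atmosphere-proportioned N2 inventory (85,000 mol N2 per 5.56e7 mol
H2O), seawater Na/Mg/Ca (0.4686/0.05282/0.01028 mol/kg, Cl⁻ balancing),
phosphate added as NaH2PO4:Na2HPO4 in a 4:1 mole ratio, and an excess
H2S/Na2S buffer holding pH in [7.6, 7.9] (target 7.8). The thermodynamic
database (`inst/extdata/thermo_db.tsv`, 49 species) is plain TSV with a
provenance column; solids are pinned to literature solubility products
(struvite pKsp 12.60, hydroxyapatite 58.60, farringtonite 24.70, ...), so
every equilibrium constant the model uses can be recomputed by hand from
the file.

## Worked example

```r
library(protocean)
db <- default_thermodb()

ocean <- default_early_ocean()
ocean$mg_ca_ratio_override <- 10000   # Mg/Ca molar ratio of the water mass
ocean$ammonium_molality    <- 0.2     # mol/kg reduced nitrogen
state <- solve_equilibrium(build_composition(calibrate_buffer(ocean, db)), db)
state
#> <equilibrium_state>
#>   pH 7.7988 | water 55.5056 mol | total G -15050.1 kJ
#>   solids: Struvite
#>   gas (bar): N2(g)=0.968, H2O(g)=0.0317, NH3(g)=0.000118, HCl(g)=4.8e-15
#>   major solutes (mol/kg): Na+=7.2, HS-=6.92, H2S(aq)=1.08, Cl-=0.595,
#>     NH4+=0.193, Mg+2=0.0631, NH3(aq)=0.00681, N2(aq)=0.00063

saturation_index(state, "Hydroxyapatite", db)
#> [1] -5.66
```

At Mg/Ca 10,000 with 0.2 mol/kg ammonium the equilibrium assemblage is
struvite alone (SI = 0) while hydroxyapatite is 5.7 log units
undersaturated — calcium is too dilute to compete. Where is the Mg/Ca
boundary at ample ammonium?

```r
tmpl <- default_early_ocean()
tmpl$ammonium_molality <- 0.5
find_threshold(tmpl, "mg_ca_ratio", struvite_present,
               bracket = c(10, 1e5), db = db)
#> <threshold_result> mg_ca_ratio = 384.233 (assemblage predicate)
#>   bracket [384.125, 384.341], rel width 0.000562, 14 bisections
```

So struvite first enters the assemblage near Mg/Ca ≈ 384 (modern seawater
sits at ≈ 5.1, hopelessly far below), and two-parameter maps of the same
machinery (`sweep_phasemap()`) trace the full phase diagram.

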