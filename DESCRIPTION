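Package: protocean
Title: Thermodynamic Equilibrium Modelling of Phosphate Minerals in an Early-Ocean Water Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes aqueous speciation and phosphate-mineral precipitation
    in a closed model ocean at 298.15 K and 1 bar by law-of-mass-action
    Newton iteration on element potentials with an active-set loop over
    candidate solids (the dual of Gibbs energy minimization under mass
    balance). Ships a pinned 25 C thermodynamic database covering the
    Na-Cl-Mg-Ca-N-S-P system, a scenario generator for a sulfide-buffered
    early-ocean water mass, and a phase-map engine that sweeps Mg/Ca ratio,
    ammonium, total phosphate and hydrogen fugacity, classifies the
    equilibrium mineral assemblage (struvite versus calcium and magnesium
    phosphates), and locates phase boundaries by bisection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
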