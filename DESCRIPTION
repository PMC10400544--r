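Package: tcosa
Title: Thermodynamics-Based Cofactor Swapping Analysis for Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconfigures constraint-based metabolic models for redox-cofactor
    swapping between NAD(H) and NADP(H) (and an optional hypothetical third
    cofactor pool) and computes max-min thermodynamic driving forces (MDF and
    SubMDF) by mixed-integer linear programming. Supports reversible-reaction
    splitting, cofactor duplication and triplication, standard Gibbs energy
    defaulting and median imputation, minimal-relaxation feasibility repair,
    specificity scenarios (wild-type, single-pool, flexible, random), growth-rate
    sweeps, single-swap scans, minimal cofactor-swap MILPs, cofactor
    concentration-ratio variability analysis, and a deterministic toy-network
    generator with an exhaustive reference oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'milp-bridge.R'
    'io-toy.R'
    'io-sbml.R'
    'io-tables.R'
    'thermo.R'
    'reconfigure.R'
    'mdf-milp.R'
    'relax.R'
    'oracle.R'
    'fba.R'
    'scenario.R'
    'swaps.R'
    'ratio.R'
    'toy.R'
    'results-io.R'
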