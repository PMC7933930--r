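Package: serpinassay
Title: Quantitative Analysis of Serpin Corrector Assay Campaigns
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis layer for small-molecule corrector campaigns against
    polymerogenic serpins such as Z alpha-1-antitrypsin. Provides exact
    ternary competitive-binding equilibria and competition-curve affinity
    fitting, pseudo-first-order association kinetics, sandwich TR-FRET
    immunoassay modelling with hook-effect peak-position calibration and
    monomer/polymer deconvolution, four-parameter logistic potency fitting,
    three-state equilibrium unfolding and thermal-shift analysis, inhibitory
    stoichiometry titrations, hepatocyte intrinsic-clearance scaling, and an
    oral multiple-dose pharmacokinetic simulator with a saturable
    high-affinity circulating target sink. Seeded synthetic-data generators
    emulate every supported assay with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    deSolve,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
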