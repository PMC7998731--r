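Package: ratpbpk
Title: Rat Pharmacokinetic Characterization and Whole-Body PBPK Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete preclinical pharmacokinetic characterization
    of a small-molecule drug candidate in the rat: noncompartmental analysis of
    plasma and tissue concentration-time profiles (AUC, lambda-z, clearance,
    Vss, bioavailability), in-vitro assay analysis (Caco-2 apparent
    permeability and efflux ratio, equilibrium-dialysis protein binding,
    microsomal substrate-depletion intrinsic clearance, CYP inhibition IC50
    and drug-drug interaction screening indices), in vitro-in vivo
    extrapolation with the well-stirred liver model, urinary/fecal excretion
    mass balance, tissue partition coefficients with Rodgers-Rowland
    prediction for unsampled tissues, and a whole-body flow-limited
    physiologically based pharmacokinetic (PBPK) simulator. A synthetic-data
    module generates every input the pipeline consumes from known ground-truth
    parameters, so all stages are testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
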