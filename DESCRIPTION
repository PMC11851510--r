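Package: admetal
Title: Trace-Metal-Aware Modelling, Calibration and Dosage Optimization of
    Batch Anaerobic Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic simulation of batch anaerobic digestion with explicit
    trace-metal chemistry: Monod growth of thirteen microbial groups with
    non-competitive inhibition, enzyme-mediated hydrolysis, liquid-gas mass
    transfer, charge-balance pH speciation, and a twenty-species mineral
    precipitation network (sulfides, carbonates, phosphates, struvites).
    Includes a staged active-set calibration of all 187 model parameters
    against measured methane flow using a sequential convex separable
    approximation optimizer, a perturbation study of calibrated parameters,
    and multi-objective optimization of trace-metal dosage in the feedstock.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr
Config/testthat/edition: 3
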