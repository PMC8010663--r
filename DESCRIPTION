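Package: glucocest
Title: Simulation and Analysis of Glucose-Weighted CEST MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing glucose-weighted chemical
    exchange saturation transfer (glucoCEST) MRI experiments: a multi-pool
    Bloch-McConnell forward simulator with a cyclic
    saturation-readout-recovery steady-state model, Z-spectrum processing
    (normalisation, B0 correction, MTRasym asymmetry analysis), dynamic
    glucoCEST-enhancement (GCE) mapping during glucose infusion,
    diffusion-tensor ADC and FA maps, a seeded synthetic generator for
    phantom and rat-cohort data, and the outlier-screening, group-comparison
    and linear-regression statistics used in preclinical imaging studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    car,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
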