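Package: sasval
Title: Validation and Analysis Toolkit for Biomolecular Solution Small-Angle Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Implements the quantitative analyses required to validate and
    report biomolecular solution small-angle scattering (SAXS/SANS)
    experiments: Guinier analysis with automated range selection, the
    regularized indirect Fourier transform to the distance distribution P(r),
    Porod-invariant and volume-of-correlation based molecular-mass estimates,
    absolute-scale mass determination from I(0) with sequence-based contrast
    calculation, dimensionless Kratky and Porod-Debye flexibility diagnostics,
    model-fit statistics (reduced chi-square with analytic scaling,
    error-weighted residuals and the exact longest-run CORMAP test), neutron
    contrast-variation analysis (match point, Stuhrmann plot, parallel-axis
    decomposition, component extraction), SEC-SAS frame-series processing,
    an analytic synthetic-data generator for ground-truth testing, and a
    guideline-structured report emitter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
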