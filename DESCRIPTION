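Package: ptycrisp
Title: Subgradient-Projection Phase Retrieval for X-Ray Ptychography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and reconstruction tools for X-ray ptychography.
    Implements the sequential ptychographical iterative engines ePIE and
    rPIE together with CRISP (clipped reliable iterative subgradient
    projection), a phase-retrieval algorithm whose per-sample step size
    adapts to the residual cost through subgradient projection, with
    step-size clipping and automatic tuning of the projection threshold.
    Includes the ptychographic observation model (subpixel probe shifts,
    unitary Fourier propagation, magnitude projection), Poisson-noise
    diffraction simulation with dose scaling, phantom and probe
    generators, and evaluation metrics (R-factor, Fourier ring
    correlation, pairwise tau dispersion score, reciprocal-space probe
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    yaml,
    withr
Config/testthat/edition: 3
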