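Package: dpca
Title: Derivative-Based Principal Component Analysis for Aberration-Free
    Holographic Phase Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes phase aberrations, including higher-order cross terms
    such as astigmatism and coma, from digital holographic microscopy (DHM)
    phase images using derivative-based principal component analysis (dPCA).
    Conventional rank-1 PCA of the complex field exp(i*phase) can only
    recover aberration surfaces separable as f(x)+g(y); dPCA differentiates
    the phase so that polynomial cross terms x^k*y^l become separable,
    estimates the aberration derivative from the first principal component,
    and integrates back using saved boundary data.  Includes a synthetic DHM
    simulator (polynomial aberration surfaces, Gaussian-spot plus letter-mask
    sample phases, four-step phase-shifting holography) so every stage is
    testable without experimental data, plus phase wrapping and unwrapping
    utilities, an iterative compensation pipeline with background-flatness
    evaluation, and float TIFF, YAML and JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
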