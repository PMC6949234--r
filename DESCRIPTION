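Package: tomosgp
Title: Scaled Gradient Projection Reconstruction for Digital Breast
    Tomosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based iterative reconstruction for digital breast
    tomosynthesis (DBT). Implements matched distance-driven cone-beam
    forward and backward projectors for a C-arc acquisition geometry, a
    smoothed total-variation regularized nonnegative least-squares
    reconstruction model, and the Scaled Gradient Projection (SGP) solver
    with Barzilai-Borwein steplength alternation and Armijo backtracking.
    Includes a parametric digital breast phantom simulator with a
    signal-to-noise calibrated Gaussian noise model, reconstruction
    quality metrics (ROI statistics, line profiles, contrast, recovery
    error), chunked evaluation contracts for large volumes, raw/TIFF
    volume I/O and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
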