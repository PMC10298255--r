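Package: capsuledry
Title: Drying Kinetics of Gel-Film Capsule Shells with Moisture-Dependent Diffusivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the hot-air drying of thin polysaccharide gel films such as
    HPMC-based hard-capsule shells. Solves Fick's second law in one dimension
    with an effective moisture diffusivity that depends on local moisture
    content and temperature, using an explicit finite-difference scheme with
    stability-bounded adaptive time stepping. Fits the diffusivity law to
    drying curves by bounded multi-start least squares, compares the variable-
    diffusivity model against a constant-diffusivity benchmark via R-squared
    and RMSE, quantifies moisture from proton-density image series the way
    low-field MRI drying studies do, and generates seeded synthetic drying
    experiments and annular image phantoms so the whole pipeline is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
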