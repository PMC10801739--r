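Package: spinedyn
Title: Forward-Dynamic Multibody Simulation of Lumbar Spine Decompression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds landmark-based synthetic lumbar spine (L1-sacrum) multibody
    models with nonlinear passive elements (tension-only ligaments, six
    degree-of-freedom intervertebral disc bushings, penalty-based facet
    contacts), integrates forward-dynamic flexion protocols with a stiff ODE
    solver, performs virtual decompression surgery (unilateral and bilateral
    interlaminar fenestration, laminectomy) by ligament resection, and
    quantifies the resulting intervertebral kinetics: level-wise
    superior-inferior compression, anterior-posterior shear and
    flexion-extension moments, normalization to the intact state, level-wise
    t-tests and one-dimensional statistical parametric mapping over the motion
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
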