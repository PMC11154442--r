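Package: ufreject
Title: Solution-Friction Modelling of Protein Rejection in Open Ultrafiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the observed rejection of proteins by open ultrafiltration
    membranes using a solution-friction transport description that combines
    concentration polarization with hindered advection and diffusion inside the
    membrane. Provides closed-form rejection equations (with and without pore
    diffusion), steric and interaction-energy partition coefficients, a
    numerical two-layer boundary-value solver that serves as an independent
    check on the closed forms, Sherwood-correlation estimates of the
    polarization-layer mass-transfer coefficient, nonlinear least-squares
    estimation of sieving coefficients and mass-transfer coefficients from
    flux-rejection data (per-condition, shared and fixed mass-transfer
    strategies), nested-model comparison by F test, and a synthetic-data
    generator reproducing a pilot-scale crossflow study design for validation
    of the whole inference pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
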