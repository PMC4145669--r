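Package: sirodecarb
Title: Kinetic, Redox and Spectroscopic Analysis of Sirohaem Decarboxylase Assays
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing sirohaem decarboxylase (AhbA/B) assay data.
    Implements the two-step single-active-site kinetic model of sirohaem
    decarboxylation with competitive substrate inhibition and tight-binding
    product inhibition, progress-curve parameter estimation by nonlinear least
    squares over the simulated ODE system, one-electron Nernst analysis of haem
    redox titrations, pyridine haemochrome difference spectroscopy with
    alpha-band peak location and haem typing, and HPLC chromatogram peak
    assignment. Includes synthetic-data generators emulating each assay so the
    full pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, deSolve, minpack.lm
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'kinetic-model.R'
    'kinetic-fitting.R'
    'redox-titration.R'
    'spectro.R'
    'synthetic-data.R'
    'io.R'
    'pipeline.R'
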