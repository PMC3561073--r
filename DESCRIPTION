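Package: bach3d
Title: Bayesian 3D Chromatin Structure Inference from Hi-C Contact Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian reconstruction of consensus three-dimensional chromatin
    structures from binned Hi-C contact matrices (the BACH model), and
    mixture modelling of the spatial arrangements of adjacent genomic
    regions in a cell population (BACH-MIX). Hi-C counts are modelled as
    Poisson with a log-linear rate combining a power-law distance decay and
    systematic bias covariates (restriction fragment-end count, GC content,
    mappability). Inference uses Poisson-regression initialization,
    sequential importance sampling to grow an initial polymer structure, and
    a Gibbs sampler with hybrid (Hamiltonian) Monte Carlo coordinate updates.
    Also provides structure analytics: the cylinder height-to-diameter (HD)
    ratio, scale-invariant normalized RMSD superposition, sliding-window
    local alignment, a plane-separation Fisher test, a two-step
    dominant-structure test against a random-walk RMSD reference
    distribution, and a synthetic Hi-C data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
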