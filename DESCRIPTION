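Package: ljbayes
Title: Hierarchical Bayesian Calibration of the Generalized Lennard-Jones
    6-p Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian calibration of the generalized Lennard-Jones 6-p pair
    potential for noble gases. Provides a Gaussian curve-fitting likelihood
    with inferred noise scale, transitional Markov chain Monte Carlo (TMCMC)
    sampling with model-evidence estimation, a two-level hierarchical layer
    that shares prior information across thermodynamic conditions, local
    kriging surrogates that replace expensive objective evaluations inside
    the sampler, evidence-based model selection between the classical 6-12
    and the generalized 6-p forms, and robust posterior prediction of
    observable curves. Closed-form forward models (dimer binding energy and
    a dilute-gas radial distribution function) make the whole pipeline
    testable at desk scale, while an adapter contract allows an external
    molecular-dynamics engine to stand behind the same interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
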