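Package: eggsig
Title: Egg Signatures, Mimicry Fidelity and Brood-Parasite Rejection Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the fidelity of avian egg mimicry and the defensive
    value of polymorphic host egg "signatures". Converts eggshell reflectance
    spectra to avian cone-catch values and receptor-noise-limited colour
    distances (JNDs), measures eggshell pattern from images (adaptive
    thresholding, granularity band-pass energies, multi-scale blob
    detection), compares host and parasite phenotype distributions
    (repeatability, rank tests, jack-knifed discriminant analysis), fits
    binomial models of host egg rejection as a function of multidimensional
    pattern distance, and runs Monte-Carlo parasitism simulations including
    a monomorphic-population counterfactual and a fecundity projection. A
    seeded synthetic-data generator reproduces the statistical structure of
    a polymorphic host/parasite egg population so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
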