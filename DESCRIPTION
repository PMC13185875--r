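Package: helidesign
Title: Local Random-Forest Models and Genetic Algorithms for Inverse
    Design of Substituted Helicenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locality-driven modelling and inverse design of the
    substituted [6]helicene chemical space (~7e10 molecules). Molecules are
    represented as 16-position Hammett sigma-para descriptor vectors; nine
    photophysical and chiroptical properties (rotatory strengths and
    wavelengths of the main ECD bands and of the lowest-energy transition,
    transition dipole magnitudes, and the absorption dissymmetry factor
    g_abs) are predicted per query by a random forest trained only on the
    query's nearest neighbours under a weighted Euclidean distance. A
    constrained genetic algorithm searches the space for molecules that
    maximize a property, hit a target value, or satisfy joint thresholds,
    and an iterative retraining loop reaches sparsely sampled property
    regions. A seeded synthetic oracle emulating the statistical structure
    of a DFT dataset makes the whole pipeline testable end to end, and an
    interpretability layer summarizes position/substituent patterns in
    candidate sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
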