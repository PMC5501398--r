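Package: enzmech
Title: Kinetic Characterization of Bisubstrate Enzymes with Allosteric
    Activation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the kinetic characterization of two-substrate
    enzymes such as pyruvate kinase: speciation of assay mixtures into
    the free species the rate laws take (ionized phosphoenolpyruvate,
    ADP-metal complex, free divalent cation), closed-form rate laws
    (Hill saturation, rapid-equilibrium random-order bisubstrate,
    linear dead-end inhibition, hyperbolic monovalent-cation
    activation), multi-start Levenberg-Marquardt fitting of single
    curves and global grids, Cleland-style classification of
    double-reciprocal and dead-end inhibition patterns with mechanism
    inference, quantification of metabolites from stepped coupled-assay
    absorbance traces, and a seeded synthetic-data generator emulating
    the experimental designs used to characterize the Vibrio cholerae
    pyruvate kinase isozymes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
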