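Package: cortimech
Title: Coupled Fluid-Structure-Electrophysiology Model of Cochlear Micromechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain simulator of the mammalian (gerbil) cochlea that
    couples two-dimensional inviscid scala fluid dynamics, a three-dimensional
    beam finite-element model of the organ of Corti complex, and small-signal
    outer-hair-cell electrophysiology (mechano-transduction, membrane RC
    circuit, somatic and hair-bundle active forces). Provides tonotopic
    parameter interpolation, sparse harmonic solves via a block-tridiagonal
    direct solver, acoustic power-flux and dissipation metrics, cochlear input
    impedance, static stiffness probes of the organ of Corti as felt by the
    outer hair cells and their hair bundles, amplification and tuning (Q10dB)
    analyses, and parameter-sensitivity and stiffness-ratio experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
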