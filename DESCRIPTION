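Package: simbci
Title: Scalp EEG Simulation and GAN-Converted Data Augmentation for BCI Classifiers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating scalp electroencephalograms from a
    three-population neural mass model of postsynaptic membrane potential,
    propagating the source through an isotropic three-shell volume conductor
    (analytic concentric-sphere series and boundary element method), converting
    the simulated multichannel signals into practical labelled EEG with a
    conditional generative adversarial network, and measuring whether the
    converted signals improve common-spatial-pattern based brain-computer
    interface classifiers under training-data scarcity. Includes a synthetic
    recording generator emulating a four-class microexpression protocol,
    EDF+ input/output, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
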