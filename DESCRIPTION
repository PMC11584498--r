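Package: vasotone
Title: Multiscale Simulation of Nitric-Oxide-Mediated Vascular Tone Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A multiscale simulator of vascular tone regulation coupling a
    lumped-parameter (0D) cardiovascular network to a two-dimensional
    finite-element model of an arterial cross section. The wall model combines
    a fiber-reinforced hyperelastic extracellular matrix, an active-strain
    description of smooth muscle contraction, and a nitric oxide / reactive
    oxygen species reaction-diffusion system driven by the wall shear stress
    sensed at the endothelium. The two scales are coupled through a sigmoid
    pressure-area surrogate and an Aitken-Steffensen fixed-point iteration on
    the time-averaged wall shear stress, enabling simulations of basal
    homeostasis, medial calcification, endothelial dysfunction and heart-rate
    ramps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
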