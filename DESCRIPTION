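Package: offres2d
Title: Single-Pulse Off-Resonance Decoupling NMR and Deep Reconstruction
    of 1H-13C Correlation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the single-pulse off-resonance decoupling approach to
    two-dimensional heteronuclear NMR of isolated 1H-13C spin pairs (13CHD2
    methyl probes).  Provides an exact Liouvillian simulator for a scalar
    coupled two-spin system under continuous-wave 13C decoupling, a synthetic
    training-data generator that pairs difference off-resonance stacks with
    Gaussian-peak target correlation maps, a convolutional neural network
    (implemented natively with RcppArmadillo) that transforms two-channel
    off-resonance stacks into 1H-13C correlation maps, Monte-Carlo dropout
    uncertainty estimation for the reconstructions, and quantification tools
    (parabolic peak picking, ensemble Gaussian intensity fitting, shift RMSD
    benchmarking and mixture-slope analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
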