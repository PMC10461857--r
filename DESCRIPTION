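Package: lowrankSNN
Title: Low-Rank Structure in Spiking and Rate Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recurrent networks whose connectivity combines
    sparse excitatory-inhibitory random coupling with a low-rank component built
    from correlated Gaussian vector pairs. Provides samplers for jointly Gaussian
    connectivity, input and readout vectors; leaky integrate-and-fire network
    simulation with synaptic delays, refractoriness and white-noise input
    (compiled core); rate-network and reduced latent dynamics; exponential spike
    filtering; mean-field fixed-point and bifurcation analysis of the collective
    variables via Gaussian integrals; state-space geometry (projections, PCA,
    principal-component alignment); and a perceptual decision-making task with
    psychometric readout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
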