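Package: brainvae
Title: Data-Driven Whole-Brain Network Models via Amortized Variational
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns the neural mass model of a whole-brain network directly
    from parcellated functional time series. Brain regions are coupled
    through a structural connectome; the regional dynamics, a two-layer
    neural network vector field with region- and subject-specific
    parameters and a shared autoregressive external input, is inferred
    jointly with its latent states by amortized variational inference
    (a sequential variational autoencoder with LSTM encoders, trained by
    Adam with the reparameterization trick). Includes stochastic
    whole-brain simulators (Hopf bifurcation and parametric mean-field
    neural masses, Euler-Maruyama integration), synthetic connectome
    generation and preprocessing (log scaling, homotopic strengthening,
    random perturbation), a goodness-of-fit battery (parameter recovery,
    spectral and distributional similarity, functional connectivity,
    surrogates, feature regression), posterior-collapse diagnostics, and
    fixed-point/stability analysis of the learned vector field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
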