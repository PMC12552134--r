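Package: actbias
Title: Inductive Biases of Single-Unit Activation Functions in Trained Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the choice of single-unit activation
    function (ReLU, logistic sigmoid, tanh) and Dale's-law connectivity
    constraints bias the circuit solutions that continuous-time recurrent
    neural networks discover for cognitive tasks. Provides task generators
    (context-dependent decision making, Go/NoGo, memory number, 3-bit
    flip-flop), RNN initialization, simulation and gradient-based training
    with sign constraints, a Newton-type fixed-point finder with stability
    classification, geometric comparison of networks via population
    trajectories, single-unit selectivity, fixed-point and trajectory-endpoint
    configurations (regression and iterative-closest-point distances embedded
    with multidimensional scaling), latent-circuit distillation of trained
    networks into small interpretable circuits, and psychometric probes of
    out-of-distribution generalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
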