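Package: trajinfo
Title: Information Transmission in Stochastic Trajectory Responses of
    Biochemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much information the time-varying stochastic
    response of a biochemical reaction network carries about a discrete
    environmental input. Provides exact Gillespie (SSA) sampling of chemical
    master equation paths, model-based Monte-Carlo approximations of the
    mutual information for continuous-time and uniformly resampled
    trajectories, maximum a posteriori (MAP) decoding lower bounds with a
    matching confusion-matrix upper bound of Feder-Merhav type, and a suite
    of model-free decoding estimators (linear and radial-basis-function
    support vector machines, a regularized Gaussian decoder, a multilayer
    perceptron) together with k-nearest-neighbor and Gaussian-approximation
    baselines. Ships three benchmark birth-death networks and an experiment
    harness for estimator comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
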