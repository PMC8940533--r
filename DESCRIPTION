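Package: surfgpc
Title: Gaussian Process Classification on Triangulated Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic binary classification of fields defined on
    triangulated 2-manifolds. Builds Matern Gaussian-process priors directly
    on a surface from a truncated Laplace-Beltrami eigenbasis assembled with
    linear finite elements, performs fully Bayesian inference with a
    No-U-Turn Hamiltonian Monte Carlo sampler under a Bernoulli-logistic
    likelihood, and couples two correlated label sources through an
    autoregressive multi-fidelity model. Includes heat-method geodesic
    distances, farthest-point experimental designs, a geodesic
    nearest-neighbor baseline, an active-learning acquisition loop, and a
    synthetic random-field benchmark. Motivated by the problem of mapping
    regions of the atria from which fibrillation is inducible in computer
    models, using few expensive pacing simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    RSpectra,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
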