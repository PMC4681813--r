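Package: motioncomplexity
Title: Information-Theoretic Complexity of Repeated 2-D Movement Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates probability distributions over repeated two-dimensional
    hand trajectories with Gaussian-process and probabilistic-movement-primitive
    models, and scores each motion pattern with five complexity measures: the
    entropic (data-independent) term of the Gaussian-process marginal
    likelihood, the entropy of the movement-primitive predictive distribution,
    Lempel-Ziv (1976) complexity and effective measure complexity of
    grid-cell transition sequences, and across-repetition trajectory variance.
    Includes a synthetic trajectory generator with controllable spatial
    complexity and repetition variability, simulated jury rankings, and
    Spearman correlation analyses linking complexity to creativity judgments,
    plus scoring of divergent-thinking responses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
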