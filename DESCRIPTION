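Package: hhvg
Title: Homeo-Heterostatic Value Gradients: Boredom-Driven Curious Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and learning library for intrinsically motivated
    model-based agents driven by the interplay of boredom and curiosity.
    Implements a deterministic two-dimensional attractor/repeller arena in the
    Mountain-Car lineage, a locally linear (bilinear-Jacobian) Gaussian forward
    model, a Householder-covariance Gaussian meta-model whose fitting realises
    outcome devaluation, devaluation progress as intrinsic reward, stochastic
    value gradients over a discrete 11 x 11 acceleration grid, the full model
    pruning ladder of agent variants (C/B, C/PE, PG/IRS, PG/GR, P/RW, Oracle),
    an exhaustive grid-sampled oracle benchmark, and exploration metrics
    (coverage rate, coverage entropy) with a Mann-Whitney comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
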