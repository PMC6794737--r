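Package: doeopt
Title: Design-of-Experiments Optimization of Command-Line Pipeline Parameters
Version: 0.1.0
Authors@R:
    person("doeopt", "authors", email = "doeopt@example.org", role = c("aut", "cre"))
Description: Tunes parameters of multi-step command-line pipelines with a
    two-phase Design-of-Experiments strategy: a generalized subset design
    (GSD) screens a mixed quantitative/ordinal/categorical factor space at
    coarse resolution, then face-centered central composite designs drive
    iterative response-surface optimization with ordinary least squares
    surrogate models, leave-one-out Q2 model validation, Derringer-Suich
    desirability aggregation of multiple responses, and explicit design-space
    movement, shrinkage and convergence rules.  Includes a YAML-configured
    pipeline runner that renders and executes user commands, a grid-search
    baseline, and seeded mock objectives so the optimizer is testable without
    external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
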