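Package: corrank
Title: Correlation-Adjusted Gene Reranking for Two-Group Differential
    Expression
Version: 0.1.0
Authors@R: person("corrank", "developers", role = c("aut", "cre"),
    email = "corrank@example.org")
Description: Reranks candidate genes in two-group differential expression
    analysis by decorrelating their t-statistics from those of an a priori
    identified null set (the zero assumption). Implements the unpaired
    pooled-variance t and SAM-style statistics, the identified/candidate
    partition, Cholesky-based decorrelation of candidate scores against
    the identified-set correlation structure, a correlation-preserving
    spike-in simulator with known ground truth, a parametric multivariate
    Gaussian simulator, and a multi-trial false-discovery evaluation
    harness with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
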