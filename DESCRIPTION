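Package: goalnet
Title: Gene Regulatory Network Inference by Multi-Objective Goal Attainment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory networks from time-course
    and gene-knockout expression data. Fits a linear ordinary differential
    equation model of transcriptional regulation by single-objective least
    squares or by multi-objective goal-attainment optimization, in which the
    fitted interaction matrix is simultaneously pulled toward objective
    matrices built from time-delayed Spearman rank correlation or from
    knockout compendia (expression ratios and cross-mutant correlations).
    Includes a benchmark generator that grows signed subnetworks from a
    scale-free source topology and simulates noisy wild-type and knockout
    expression with Hill-kinetics or linear dynamics, polynomial
    interpolation of replicated time courses, undirected and directed-signed
    ROC evaluation of inferred networks, and an orchestrated benchmark that
    scores all inference procedures over batches of simulated networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
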