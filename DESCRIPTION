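Package: dolnet
Title: Evolution of Reproductive Division of Labor on Cellular Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of reproductive specialization in clonal
    multicellular groups whose cells share viability returns across an
    interaction network. Provides graph generators and edge-list/GraphML I/O,
    the weighted sharing matrix and group-fitness function with analytic
    gradient and Hessian, stability analysis of the generalist strategy
    (largest Hessian eigenvalue, analytic thresholds for named topologies, and
    the alpha-star amenability metric), numerical fitness maximization with
    specialization scoring, sparsity and phase-map parameter sweeps over random
    graphs, Wright-Fisher evolutionary simulations with fixed or evolving
    sharing, and the mean-field specialist/generalist fitness theory with
    empirical assortment measurement on concrete graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
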