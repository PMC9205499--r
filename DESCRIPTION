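Package: dnvnet
Title: Network-Assisted Identification of Risk Genes from De Novo Variant Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies disease risk genes from per-gene de novo variant (DNV)
    counts in trio sequencing cohorts by borrowing strength across a
    protein-protein interaction network. A discrete Markov random field prior
    couples latent per-gene risk states over the network, DNV counts follow a
    Poisson burden model with a gene-specific mutability offset, and
    hyperparameters are estimated empirically by maximizing a pseudo
    conditional likelihood (penalized logistic fit, iterated conditional
    modes, and a closed-form relative-risk estimator). Posterior probabilities
    of non-association are computed by Gibbs sampling and thresholded with a
    cumulative local-fdr rule that controls the global false discovery rate.
    Includes a simulation framework for power and FDR studies and a
    permutation test for edge-count enrichment of gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
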