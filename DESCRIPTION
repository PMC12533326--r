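Package: gpcca
Title: Generalized Probabilistic Canonical Correlation Analysis for
    Multi-Modal Data with Full or Partial Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic canonical correlation analysis generalized to two
    or more data modalities measured on a shared set of samples, with a
    block-diagonal error covariance that allows residual correlations within
    a modality but not across modalities. Parameters are estimated by an EM
    algorithm that natively handles entry-wise and modality-wise missing
    data through per-subject partial-observation algebra, with ridge
    shrinkage of the error correlation matrix for stability in high
    dimensions. Includes consensus-based selection of the number of latent
    factors over repeated initializations, Louvain clustering of the latent
    embeddings on a shared-nearest-neighbor graph, adjusted Rand index and
    normalized mutual information for evaluating partitions, a synthetic
    multi-modal data generator covering Gaussian and heavy-tailed designs
    with MCAR and modality-wise MNAR missingness, and delimited-text
    readers/writers plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
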