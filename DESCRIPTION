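Package: saomnet
Title: Dynamic Social Network Analysis with Stochastic Actor-Oriented Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the dynamics of animal social networks
    observed as panel data. Converts scan-sampling association records into
    binary "mutual preferred social partner" networks via a mean-plus-a-third
    standard-deviation threshold applied to grooming and proximity matrices,
    ranks individuals by the I&SI dominance criterion, and models network
    change with a continuous-time stochastic actor-oriented model featuring
    triadic closure, degree popularity, covariate homophily and covariate
    rate effects. Parameters are estimated by method of moments with
    three-phase Robbins-Monro stochastic approximation; inference uses
    Wald-type tests and stepwise effect selection, and model adequacy is
    assessed by a Monte Carlo Mahalanobis distance test on degree, geodesic
    and triad-census distributions. A synthetic-data generator with known
    ground truth supports calibration and recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
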