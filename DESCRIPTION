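Package: wallconf
Title: Partition Coefficient and Configurational Entropy of Dumbbells Near a Wall
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical mechanics of N coarse-grained dumbbell molecules
    confined by a hard flat wall, resolved by their conformation tensor.
    Computes the confined-to-unconfined partition-function ratio (the
    partition coefficient W) and the confinement-induced configurational
    entropy change, via closed-form limit laws, deterministic quadrature
    oracles for small systems, direct and shell Monte Carlo estimators,
    Wang-Landau flat-histogram sampling with a t^-1 refinement schedule,
    and power-law / interpolating-function fitting of the onset and
    saturation regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
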