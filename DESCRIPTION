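Package: coralpp
Title: Spatial Point Process Analysis of Benthic Cup Coral Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring recruitment and dispersal dynamics of sessile
    benthic organisms from annotated seabed photographs.  Implements kernel
    estimation of the pair correlation function with translation or isotropic
    edge correction on rectangular sampling windows, fitting of homogeneous
    Poisson (CSR), heterogeneous Poisson, Thomas cluster and substrate-thinned
    Thomas cluster models by minimum contrast, Monte Carlo simulation envelopes
    with Diggle's goodness-of-fit rank test, reproductive-cluster diagnostics
    (offspring per non-empty cluster, cluster-membership probability),
    nearest-neighbour summaries, Bray-Curtis community grouping, and a
    synthetic-study generator so that the whole pipeline can be exercised
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    vegan,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
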