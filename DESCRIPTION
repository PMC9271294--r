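Package: psychatlas
Title: Self-Organizing Psychotype Atlas with Well-Being Overlays and
    Attitude-Change Recommendations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains Kohonen self-organizing maps on questionnaire-derived
    psychometric profiles, overlays depression odds and well-being metadata on
    the resulting cell grid, clusters the codebook into psychotypes, and
    computes weighted shortest paths across the map that translate into ranked
    attitude-change recommendations.  Also provides feed-forward regressors for
    psychological age and future well-being with cross-validated evaluation,
    shadow-feature (Boruta-style) relevance selection with a variance-inflation
    collinearity screen, elastic-net relative-importance analysis, and a seeded
    generator of midlife-cohort-like synthetic data so the whole pipeline can
    be exercised without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
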