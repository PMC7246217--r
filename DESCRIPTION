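Package: seascapr
Title: Seascape Population Genomics: Barriers, Distance, Environment and
    Divergence History from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end seascape genomics toolkit for reef organisms
    sampled along a coastline: genotype ingestion and locus filtering,
    diversity statistics and Weir-Cockerham FST, least-cost within-water
    geographic distances, environmental PCA distances and discrete barrier
    codings, multi-model inference over isolation-by-barrier /
    isolation-by-distance / isolation-by-environment hypotheses via multiple
    matrix regression with randomization (MMRR) ranked by AICc, an FST
    outlier scan based on a trimmed chi-square null, and folded joint
    site-frequency-spectrum comparison of two-population divergence models
    (SI, IM, AM, SC and heterogeneous-migration variants) with expected
    spectra from a structured-coalescent simulator. A synthetic-data
    generator produces seascapes, environments and genotypes with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
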