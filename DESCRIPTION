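Package: deadwoodlinks
Title: Cross-Taxon Association Networks for Paired Deadwood Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired site-by-taxon community matrices of
    wood-inhabiting fungi and saproxylic beetles sampled from the same forest
    plots. Provides alpha-diversity and rarefaction summaries (exponential
    Shannon, individual- and sample-based rarefaction), partial canonical
    correspondence analysis with an ANOVA-like permutation test of management
    and stratum effects conditioned on region, co-inertia analysis with the RV
    coefficient and its permutation test, and permutation-based Spearman
    cross-correlation network inference between the two taxon groups with
    Benjamini-Hochberg false-discovery-rate control. A synthetic community
    generator with copula-planted beetle-fungus associations supplies
    ground-truth data for calibration and recovery experiments.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
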