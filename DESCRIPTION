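Package: aquagap
Title: Conservation Gap Analysis for Freshwater Insect Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for conservation gap
    analysis of freshwater insect assemblages (such as the semi-aquatic
    Gerromorpha): occurrence cleaning on a decimal-degree grid, principal
    component compression of collinear bioclimatic layers, presence-background
    species distribution models evaluated by AUC and the true skill statistic
    and binarized at the max-TSS threshold, richness and pairwise beta
    diversity partitioned into turnover and nestedness with PCoA
    spatialization, Monte Carlo randomization tests against biome and
    protected-area cell sets, greedy additive-benefit reserve prioritization,
    and a logistic estimate of the minimum range size a species needs to fall
    inside the protected-area network. A synthetic landscape generator with
    known ground truth replaces field data so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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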