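Package: gammapop
Title: Micropollutant Burden and Population-Genetic Diversity in River
    Amphipods
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit linking anthropogenic organic micropollutant (AOM)
    burden to the population-genetic diversity of river macroinvertebrates
    sampled along pollution gradients. Converts tissue chemistry into
    toxic units via equilibrium partitioning and LC50 aggregation;
    computes per-site microsatellite diversity statistics (observed and
    unbiased expected heterozygosity, inbreeding coefficients, rarefied
    allelic and private-allele richness, Monte-Carlo Hardy-Weinberg
    tests, null-allele screening, linkage-disequilibrium effective
    population size); estimates Weir-Cockerham pairwise F_ST with
    permutation nulls, hierarchical AMOVA, and Mantel / partial Mantel
    spatial association; and fits random-intercept linear mixed models
    with AICc all-subsets selection plus recursive path models. A
    forward Wright-Fisher stepping-stone simulator generates complete
    synthetic study bundles (genotypes, chemistry, LC50, metadata,
    waterway distances) emulating a multi-river, multi-catchment survey
    design so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vegan,
    withr
Config/testthat/edition: 3
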