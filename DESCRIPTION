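Package: gidscan
Title: Gene-Gene Interaction Scanning for Multi-Class Phenotypes with the
    Generalized Index of Dissimilarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene-gene interactions (epistasis) when the phenotype has
    an arbitrary number of outcome classes. Association between a multi-locus
    genotype and a multi-class phenotype is measured by the generalized index
    of dissimilarity (GIDS), a normalized sum of absolute deviations between
    observed and independence-expected counts in the 3^k x J genotype-by-
    phenotype contingency table. For two outcome classes GIDS reduces to the
    classical index of dissimilarity and is analytically equivalent to the
    balanced accuracy used by multifactor dimensionality reduction (MDR),
    without requiring per-genotype risk statuses. Provides exhaustive k-locus
    scans, max-statistic permutation p-values with best-model selection across
    interaction orders, a Pearson chi-squared baseline, penetrance-driven
    categorical and Gaussian-mixture quantitative phenotype simulators, trait
    categorization rules, a composite blood-pressure classifier, and harnesses
    for power (hit ratio) and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
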