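Package: pcbmr
Title: Principal-Component-Based Multivariate Regression for Gene
    Pleiotropy Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether a genetic marker is associated with several
    correlated quantitative traits at once.  Traits are standardized,
    the eigendecomposition of their correlation matrix yields mutually
    uncorrelated canonical variables, and a summed per-component
    likelihood-ratio statistic with a chi-squared calibration tests all
    marker effects jointly (PCBMR).  The package also provides
    single-trait comparators with and without Bonferroni adjustment,
    genotype quality control including an exact Hardy-Weinberg test,
    simulation generators for pleiotropic quantitative-trait
    architectures (direct QTL effects, linkage-disequilibrium-linked
    markers, competing QTL and environmental effects, many correlated
    traits), a Monte-Carlo power engine with a paired binomial exact
    power comparison, and a command-line scan front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
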