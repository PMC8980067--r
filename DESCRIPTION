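Package: gxescore
Title: Molecular Gene-Environment Scores and Brain-Structure Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives molecular measures of genetic and environmental risk for
    bipolar-spectrum disorder and relates them to structural brain measures.
    Implements genotype quality control (exact Hardy-Weinberg test, call-rate
    and frequency filters, identity-by-descent relatedness), LD clumping and
    polygenic risk scoring over a p-value-threshold grid with logistic
    threshold selection; methylation probe/sample quality control, beta-mixture
    quantile (BMIQ) normalisation, M-value transformation and a LASSO-based
    methylation profile score; covariate-adjusted main-effect and
    gene-environment interaction regressions on brain measures with partial
    R-squared, bootstrap model comparison, Storey q-value false discovery
    rates and a cis-meQTL scan. A synthetic-cohort generator with planted
    genetic, epigenetic and interaction effects makes every stage testable
    without access to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
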