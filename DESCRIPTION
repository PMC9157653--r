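Package: gsolanum
Title: Genomic Selection for Fruit Traits in Solanaceous Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genomic-selection toolkit for tomato- and pepper-style
    diversity panels: genotype quality control and LD-based tag-SNP
    selection, trial-level BLUP phenotypes with heritability from a
    two-random-effect REML mixed model, single-trait ridge-regression BLUP
    (rrBLUP/GBLUP) and multivariate kinship-based genomic prediction,
    classification-based prediction of ordinal descriptor traits with
    SMOTE class balancing, and a repeated cross-validation engine with the
    predictability metrics and population-transfer scenarios used in
    Solanaceous fruit-trait studies. Includes a seedable synthetic-data
    generator (Balding-Nichols population structure, autoregressive LD,
    polygenic traits with trial/replicate structure) for end-to-end
    testing without access to real panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    lme4,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
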