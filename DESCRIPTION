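Package: lipidtract
Title: Serum Lipidome Associations with White-Matter Microstructure after
    Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline linking quantitative serum lipidomics to
    region-of-interest diffusion MRI metrics (fractional anisotropy, mean
    diffusivity) and regional brain volumes after traumatic brain injury.
    Provides reference-anchored ComBat harmonization of scanner effects,
    normative (age- and sex-adjusted) abnormality scoring and burden-of-injury
    percentages, Holm-filtered lipid-by-ROI Pearson correlation frequency
    analysis, two-stage feature-filtered penalized logistic classification of
    MRI positivity, covariate-controlled partial-correlation networks over
    lipids and white-matter tracts, and a synthetic cohort generator with
    planted ground truth for validating every stage.
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
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
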