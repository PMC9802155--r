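Package: fermrsm
Title: Box-Behnken Response-Surface Optimization of Fermentation Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designed-experiment optimization of microbial
    fermentation media: Box-Behnken designs with coded/actual factor
    transforms, full second-order response-surface model fitting by
    ordinary least squares, ANOVA with partial (Type III) sums of squares
    and a lack-of-fit/pure-error split, constrained maximization of the
    fitted quadratic surface over the coded design cube, and the
    supporting bioassay statistics used in probiotic strain screening
    (DPP-IV inhibition rates, indole-3-acetic acid quantification against
    a standard curve, acid/bile-salt survival rates, and two-group
    seedling growth-promotion tests). Ships the 29-run spore-yield
    dataset for Bacillus licheniformis FYN-22 as a worked fixture, and
    simulators with known ground truth for every input the pipeline
    consumes.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
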