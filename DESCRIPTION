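Package: twinclock
Title: Epigenetic and Brain Age Acceleration in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking blood DNA-methylation age acceleration from
    linear epigenetic clocks to structural-MRI brain age acceleration in
    family-based (twin) samples. Provides a generic clock engine for
    user-supplied CpG coefficient tables, age-bias correction of the brain-age
    gap, generalized extreme studentized deviate (Rosner) outlier screening,
    family-clustered linear mixed models with base/full/sensitivity covariate
    sets, and the classical twin-design aetiology decomposition (cross-twin
    cross-trait correlations and monozygotic-twin difference regression).
    Includes a synthetic twin-cohort generator with a known bivariate ACE
    latent structure so every pipeline stage is testable without restricted
    cohort data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
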