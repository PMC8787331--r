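Package: dnamtraj
Title: DNA Methylation Age Acceleration Trajectories in Serial Cerebrospinal Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes DNA methylation (DNAm) age from epigenetic clock
    coefficient tables (Horvath, Hannum, Levine, Zhang conventions), derives
    residual-based age acceleration within cross-sectional time windows with
    optional adjustment for reference-free cell-type heterogeneity estimates,
    and fits group-based trajectory models (finite mixtures of polynomial
    trajectories with a censored-normal observation model) to acceleration
    over the acute recovery period after aneurysmal subarachnoid hemorrhage.
    Includes a synthetic-cohort generator with planted clock signal and
    latent trajectory groups so the whole pipeline is testable without
    patient data, BIC-based model search, posterior classification quality
    control, and the descriptive and bivariate statistics used to profile
    trajectory groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
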