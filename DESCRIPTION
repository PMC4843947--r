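Package: fcentropy
Title: Functional Connectivity Entropy over Structural Path Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Couples diffusion-tractography structure to resting-state
    functional connectivity in region-parcellated brain networks.  Region
    pairs are classified by shortest structural path order (primary,
    secondary, tertiary) from binarized streamline-count matrices, and the
    spatial variability of functional connectivity within each class is
    quantified as the Shannon entropy of the binned distribution of
    pairwise Pearson correlations (functional connectivity entropy, FCE).
    Includes covariate residualization, two-sample effect-size statistics
    and symptom correlations for patient/control cohorts, a streamline
    threshold sensitivity sweep, and a synthetic-cohort generator with
    designed ground-truth effects for calibration, type-I-error and
    power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
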