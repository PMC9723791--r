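Package: traitscaper
Title: Trait-Scape Analysis of Multivariate Phytoplankton Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds reduced-dimensionality "trait-scapes" from multivariate
    phytoplankton trait data: derives phenotypic traits from instrument-level
    measurements (fluorescence growth series, rapid light curves, bead-calibrated
    flow cytometry), standardizes traits and ordinates them by principal
    component analysis with per-axis trait contributions, identifies orthogonal
    trait groups from correlation structure, scores the recovery of the
    trait-scape from reduced trait subsets, supports hierarchical clustering of
    phenotypes with multiscale-bootstrap approximately unbiased (AU) p values,
    and quantifies multi-trait plastic responses ("strategies") across growth
    environments. Includes a latent-factor synthetic data generator with known
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
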