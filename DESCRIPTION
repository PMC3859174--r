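Package: bitterQSBR
Title: Quantitative Structure-Bitter-Taste Modelling of Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workflow for quantitative structure-bitter-taste relationship
    (QSBR) modelling of peptides. Ships a curated 227-entry peptide bitterness
    dataset (observed log(1/T) thresholds with reference model predictions),
    computes the six 3D molecular descriptors used by the published
    six-descriptor bitterness equation (SPAN, Balaban mean-square-distance,
    directional WHIM accessibility and symmetry, GETAWAY leverage
    autocorrelation, 3D-MoRSE), implements the three-stage descriptor
    selection cascade (correlation/frequency filter, iterative GA-PLS scoring,
    stepwise regression), builds MLR, epsilon-SVR and Levenberg-Marquardt
    neural-network models, and provides the full validation suite: percentage
    deviation statistics, leave-many-out cross-validation, Y-randomization and
    the Golbraikh-Tropsha / Roy external-validation criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    minpack.lm,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
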