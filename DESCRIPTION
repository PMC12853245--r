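Package: seashift
Title: Ensemble Species Distribution Models and Community Change Under
    Ocean-Climate Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for projecting benthic species range
    shifts and community change under climate scenarios: environmental
    predictor preparation (temporal aggregation, control-run detrending,
    multiplicative anomaly forcing, regridding), collinearity-aware
    predictor selection (Spearman correlation clustering and stepwise VIF
    pruning), occurrence thinning with a minimum-prevalence filter,
    target-group density-dependent and environmentally stratified
    pseudo-absence generation, a four-learner ensemble (GLM, GAM, random
    forest, neural network) fitted over a spatially blocked
    5-fold x 3-repetition x 3-replicate design and scored with AUC, TSS and
    the continuous Boyce index, scenario projection with max-TSS
    binarization, depth-window cropping and MESS extrapolation masks,
    per-species distributional shift metrics (range area, latitudinal
    centroid, depth, fragmentation) with ecological indicator values,
    stacked alpha diversity and Podani-decomposed temporal beta diversity,
    and Getis-Ord Gi* hotspot classification. A virtual-species simulator
    with analytically known niches makes every stage testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    mgcv,
    nnet,
    pracma,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
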