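Package: phytoSDM
Title: Ensemble Species Distribution Modelling of Grass Abundance from Soil Phytoliths
Version: 0.1.0
Authors@R:
    person("Soil Phytolith SDM", "Maintainers", email = "maintainers@phytosdm.example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing long-term grass abundance from soil
    phytolith content (percent dry soil mass) with ensemble species
    distribution models. Provides a synthetic-landscape simulator with
    correlated covariate blocks, site sampling and a log-scale proxy
    response; Pearson correlation screening with a coastal restricted-range
    variant and depth-weighted soil covariate integration; three abundance
    learners (a compiled regression random forest, cross-validated lasso,
    and penalized additive smooths with null-space shrinkage) with
    per-learner variable importance; k-fold cross-validation with
    correlation-derived ensemble weights and a full metric suite; spatial
    diagnostics (Moran's I permutation test on residuals, cross-model
    residual correlation, principal-component environmental-novelty
    distance with masking, NPP detrending, correlation-distance variable
    clustering); a closed-form phytolith accumulation-time model; and a
    configurable end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    mgcv,
    jsonlite,
    withr,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
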