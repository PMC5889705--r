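Package: pinyon
Title: Forest-Cover Mapping, Error-Adjusted Area Estimation and
    Presence Modelling for Arid Pinyon Woodlands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for supervised land-cover mapping of arid pinyon
    woodland from a multiband reflectance stack and for design-based
    accuracy and area estimation from the resulting error matrix. A
    seeded synthetic-landscape generator (DEM, coarse climate
    covariates, cover truth, reflectance bands, stratified reference
    samples) makes the whole workflow testable offline. Includes terrain
    ruggedness metrics (TRI, VRM), NDVI and band stacking, a one-hidden-
    layer backpropagation neural-network pixel classifier, poststratified
    estimators of class proportions and error-adjusted areas with
    analytic standard errors, user's/producer's/overall accuracy and
    kappa, and a presence/absence association stage (Kruskal-Wallis
    screening with Bonferroni correction, Spearman collinearity pruning,
    binomial logistic regression, cross-validated random forest with
    AUC/TSS/kappa/sensitivity/specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC
Config/testthat/edition: 3
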