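Package: nichecast
Title: Ensemble Species Distribution Modelling and Pest-Risk Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for climate-envelope based pest-risk analysis: collinearity
    filtering of bioclimatic predictors (Ward clustering of a correlation
    distance plus variance-inflation-factor screening), presence-only
    environmental envelopes with background and pseudoabsence partitioning,
    a six-algorithm ensemble species distribution model (GLM, GAM, neural
    network, classification tree, MaxEnt-style regularised logistic, random
    forest) with consensus and bound suitability maps and ROC/AUC evaluation,
    niche contrasts between presence and no-record locations, overlap of
    modelled suitability with categorical crop-suitability maps, and field
    survey statistics (clumped count diagnostics, binary and ordered logistic
    regressions). Includes synthetic-landscape generators that emulate the
    statistical structure of all required inputs so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    nnet,
    rpart,
    randomForest,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
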