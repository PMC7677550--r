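Package: stresswalk
Title: Predicting Stress-Evoked Vagal Withdrawal from Exploratory Locomotion
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for digital behavioral phenotyping of stress vulnerability.
    Processes ECG and respiration waveforms into time-domain heart rate
    variability summaries (RMSSD, SDNN, HRV triangular index), builds an
    integrated HRV index (iHRV) as a respiration-decontaminated principal
    component of cardiorespiratory variables, extracts locomotor feature
    families (position, gait, movement bursts) from head tracking and lower
    body motion capture recorded during virtual open-field and elevated-alley
    exploration, selects predictive features with a zero-variance / Spearman /
    per-family Lasso cascade, and fits gradient-boosted regression trees with
    Bayesian (TPE) hyperparameter tuning and exact tree-SHAP attributions to
    predict stress-evoked cardiac vagal withdrawal. A synthetic-cohort
    generator with a latent vulnerability trait provides ground-truthed data
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
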