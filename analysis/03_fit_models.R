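#!/usr/bin/env Rscript
# Step 3 — the three diagnostic model tiers.
#
# Traditional tier: univariate screen (p < 0.10) feeding stepwise logistic
# regression. Radiomic tier: the t-test + AUC > 0.65 gate per sequence, then
# the 10-tree depth-3 random forest on the union of T1 and CE-T1 features.
# Combined tier: the forest additionally given IPH, MLA, enhancement ratio
# and the traditional linear predictor. Resubstitution operating points via
# Youden's J, pairwise DeLong comparisons, and a 5-fold cross-validated AUC
# as an honesty check on resubstitution optimism.

library(plaquerad)

seed <- 1L
conv <- read.csv("results/conventional_metrics.csv", stringsAsFactors = FALSE)
features <- read.csv("results/radiomic_features.csv", stringsAsFactors = FALSE)

analysis <- run_analysis(conv, features, sequences = c("T1", "CE_T1"),
                         seed = seed, cv_folds = 5L)
tabs <- report_tables(analysis, conv, features, dir = "results/tables")

message("univariate screen (p < 0.10 candidates):")
print(subset(tabs$univariate, p_value < 0.10))
message("stepwise logistic selection:")
print(tabs$multivariate)
message(sprintf("radiomic features selected: %d on T1, %d on CE-T1",
                length(analysis$radiomic$selected$T1),
                length(analysis$radiomic$selected$CE_T1)))
t2_sel <- select_radiomic_features(
  features[grep("^T2_", names(features))], features$label)
message(sprintf("T2-only selection: %d features", length(t2_sel)))
message("diagnostic performance (resubstitution; cv_auc is 5-fold):")
print(tabs$diagnostics)
message("note: resubstitution AUCs are optimistic; compare the cv_auc column")
print(tabs$delong)

if (!is.null(analysis$radiomic$model)) {
  forest_to_json(analysis$radiomic$model, "results/radiomic_forest.json")
}
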