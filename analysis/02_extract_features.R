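#!/usr/bin/env Rscript
# Step 2 — conventional plaque metrics and the radiomic feature catalogue.
#
# Reads the cohort written by 01_simulate_cohort.R back from its NIfTI
# files, computes the traditional measurements (plaque burden, MLA,
# stenosis, IPH by the 150% muscle rule, grey-matter-normalised enhancement
# ratio) and extracts the 98-feature radiomic catalogue per sequence
# (32 grey levels, distance-1 co-occurrence over four directions).

library(plaquerad)

cohort <- read_cohort("results/cohort")
message(sprintf("read %d studies", length(cohort)))

conv <- cohort_conventional(cohort)
write.csv(conv, "results/conventional_metrics.csv", row.names = FALSE)

features <- cohort_features(cohort)
write.csv(features, "results/radiomic_features.csv", row.names = FALSE)

jsonlite::write_json(feature_catalogue(), "results/feature_manifest.json")

sym <- conv$label == "acute_subacute_symptomatic"
message(sprintf("IPH prevalence: %d/%d symptomatic vs %d/%d asymptomatic",
                sum(conv$iph[sym]), sum(sym), sum(conv$iph[!sym]), sum(!sym)))
message(sprintf("MLA (mm^2): %.2f vs %.2f; enhancement ratio: %.1f%% vs %.1f%%",
                mean(conv$mla[sym]), mean(conv$mla[!sym]),
                mean(conv$enhancement_ratio[sym]),
                mean(conv$enhancement_ratio[!sym])))
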