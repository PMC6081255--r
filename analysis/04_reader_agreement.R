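#!/usr/bin/env Rscript
# Step 4 — inter-reader reproducibility.
#
# Emulates a second reviewer on a random 40-patient subset by jittering the
# segmentation boundaries, then quantifies agreement: ICC(2,1) (two-way
# random, absolute agreement, single measure) and Bland-Altman limits for
# the traditional measurements and the group-discriminating radiomic
# features, and Cohen's kappa for the binary IPH call.

library(plaquerad)

seed <- 1L
cohort <- read_cohort("results/cohort")

set.seed(seed + 101)
idx <- sample(length(cohort), 40)
reader1 <- cohort[idx]
reader2 <- lapply(seq_along(idx), function(i)
  perturb_segmentation(cohort[[idx[i]]], jitter_scale = 1,
                       seed = seed + 200 + i))

conv1 <- cohort_conventional(reader1)
conv2 <- cohort_conventional(reader2)
trad_vars <- c("stenosis_percent", "plaque_burden", "mla", "enhancement_ratio")
tab <- do.call(rbind, lapply(trad_vars, function(v)
  data.frame(subject = conv1$patient_id, measurement = v,
             reader1 = conv1[[v]], reader2 = conv2[[v]])))
trad <- agreement_summary(tab)
print(trad$per_measurement)
message(sprintf("average ICC, traditional measurements: %.3f",
                trad$average_icc))
message(sprintf("Cohen's kappa for IPH: %.3f",
                cohens_kappa(conv1$iph, conv2$iph)))

feat_names <- c(paste0("T1_", c("shape_Maximum3DDiameter",
                                "shape_Maximum2DDiameterSlice", "shape_Volume",
                                "shape_SurfaceArea",
                                "shape_Maximum2DDiameterColumn",
                                "glcm_Entropy",
                                "glrlm_RunLengthNonUniformity")),
                paste0("CE_T1_", c("firstorder_Uniformity",
                                   "glcm_MaximumProbability", "glcm_Entropy")))
f1 <- cohort_features(reader1, sequences = c("T1", "CE_T1"))
f2 <- cohort_features(reader2, sequences = c("T1", "CE_T1"))
rtab <- do.call(rbind, lapply(feat_names, function(v)
  data.frame(subject = f1$patient_id, measurement = v,
             reader1 = f1[[v]], reader2 = f2[[v]])))
rad <- agreement_summary(rtab)
print(rad$per_measurement)
message(sprintf("average ICC, radiomic features: %.3f", rad$average_icc))

dir.create("results", showWarnings = FALSE)
write.csv(rbind(trad$per_measurement, rad$per_measurement),
          "results/agreement_icc.csv", row.names = FALSE)
ba <- bland_altman(conv1$mla, conv2$mla)
write.csv(ba$points, "results/bland_altman_mla.csv", row.names = FALSE)
jsonlite::write_json(
  list(average_icc_traditional = trad$average_icc,
       average_icc_radiomic = rad$average_icc,
       kappa_iph = cohens_kappa(conv1$iph, conv2$iph)),
  "results/agreement_summary.json", auto_unbox = TRUE, digits = NA)
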