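Package: plaquerad
Title: Radiomic Texture Analysis of Basilar Artery Plaque on Vessel-Wall MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for discriminating acute/sub-acute symptomatic
    from asymptomatic basilar-artery atherosclerotic plaque on high-resolution
    vessel-wall MRI. Provides a synthetic plaque-image cohort generator,
    conventional plaque measurements (plaque burden, minimal luminal area,
    intraplaque haemorrhage detection, contrast enhancement ratio, stenosis),
    a from-scratch 2D radiomic feature engine (first-order, shape, grey-level
    co-occurrence, run-length and size-zone texture features), univariate
    screening and stepwise logistic regression, a shallow random-forest
    classifier, ROC/AUC machinery with DeLong comparison of correlated curves,
    and inter-reader agreement statistics (ICC, Bland-Altman, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
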