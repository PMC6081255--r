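# Synthetic cohort generator: determinism, structural invariants, and
# recovery of the specified group statistics.

test_that("cohort generation is reproducible and respects group sizes", {
  sp <- cohort_spec(n_symptomatic = 6L, n_asymptomatic = 4L, seed = 7L)
  coh1 <- generate_cohort(sp)
  coh2 <- generate_cohort(sp)
  expect_length(coh1, 10L)
  expect_equal(sum(vapply(coh1, function(s) s$label, "") ==
                     "acute_subacute_symptomatic"), 6L)
  expect_identical(coh1, coh2)          # bit-identical from the same seed
  coh3 <- generate_cohort(cohort_spec(n_symptomatic = 6L, n_asymptomatic = 4L,
                                      seed = 8L))
  expect_false(identical(coh1, coh3))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_symptomatic = 0), "n_symptomatic")
  expect_error(cohort_spec(iph_prevalence = c(1.2, 0)), "probabilities")
  expect_error(cohort_spec(pixel_spacing = -1), "positive")
  expect_error(cohort_spec(texture_heterogeneity = c(-0.1, 0.5)),
               "heterogeneity")
  expect_error(generate_cohort(list()), "cohort_spec")
})

test_that("masks satisfy the geometric invariants", {
  coh <- generate_cohort(cohort_spec(n_symptomatic = 8L, n_asymptomatic = 8L,
                                     seed = 3L))
  for (st in coh) {
    m <- st$masks
    expect_false(any(m$lumen & !m$outer_wall))          # lumen inside wall
    expect_identical(m$plaque_roi, m$outer_wall & !m$lumen)
    expect_false(any(m$muscle_ref & m$outer_wall))
    expect_false(any(m$grey_matter_ref & m$outer_wall))
    expect_true(any(m$plaque_roi))
    gm_area <- mask_area(m$grey_matter_ref, st$images$T1$pixel_spacing)
    expect_gt(gm_area, 13); expect_lt(gm_area, 17)      # ~15 mm^2 reference
  }
})

test_that("forced iph prevalence puts a detectable blob in symptomatic studies only", {
  sp <- cohort_spec(n_symptomatic = 6L, n_asymptomatic = 6L,
                    iph_prevalence = c(1, 0), seed = 11L)
  coh <- generate_cohort(sp)
  cm <- cohort_conventional(coh)
  sym <- cm$label == "acute_subacute_symptomatic"
  expect_true(all(cm$iph[sym]))
  expect_false(any(cm$iph[!sym]))
})

test_that("zero texture heterogeneity renders a constant annulus", {
  sp <- cohort_spec(n_symptomatic = 1L, n_asymptomatic = 1L,
                    texture_heterogeneity = c(0, 0),
                    t2_texture_heterogeneity = 0,
                    iph_prevalence = c(0, 0), seed = 5L)
  coh <- generate_cohort(sp)
  fv <- extract_features(coh[[1]], sequences = "T2")
  expect_equal(unname(fv$T2["glcm_Entropy"]), 0)
  expect_equal(unname(fv$T2["firstorder_StandardDeviation"]), 0)
})

test_that("rendered enhancement ratio recovers the drawn value", {
  coh <- generate_cohort(cohort_spec(n_symptomatic = 10L, n_asymptomatic = 10L,
                                     seed = 13L))
  cm <- cohort_conventional(coh)
  drawn <- vapply(coh, function(s) s$drawn$enhancement_ratio, 0)
  expect_true(all(abs(cm$enhancement_ratio - drawn) < 2))
})

test_that("extracted group means track the spec at n = 200 per group", {
  sp <- cohort_spec(n_symptomatic = 200L, n_asymptomatic = 200L, seed = 17L)
  coh <- generate_cohort(sp)
  cm <- cohort_conventional(coh)
  sym <- cm$label == "acute_subacute_symptomatic"
  for (g in 1:2) {
    rows <- if (g == 1) sym else !sym
    mla_t <- sp$mla_mean_sd[[g]]
    er_t <- sp$enhancement_mean_sd[[g]]
    expect_lt(abs(mean(cm$mla[rows]) - mla_t[1]), 2 * mla_t[2] / sqrt(200))
    expect_lt(abs(mean(cm$enhancement_ratio[rows]) - er_t[1]),
              2 * er_t[2] / sqrt(200))
    # empirical IPH prevalence within binomial 95% bounds of the target
    p <- sp$iph_prevalence[g]
    half <- 1.96 * sqrt(p * (1 - p) / 200)
    expect_lt(abs(mean(cm$iph[rows]) - p), half + 0.015)
  }
})

test_that("mean glcm entropy increases with texture heterogeneity", {
  ents <- vapply(c(0.4, 0.7, 1.0), function(h) {
    sp <- cohort_spec(n_symptomatic = 50L, n_asymptomatic = 1L,
                      texture_heterogeneity = c(h, h),
                      iph_prevalence = c(0, 0), seed = 31L)
    coh <- generate_cohort(sp)
    mean(vapply(coh[1:50], function(st)
      extract_features(st, sequences = "T1")$T1[["glcm_Entropy"]], 0))
  }, 0)
  expect_true(all(diff(ents) > 0))
})

test_that("segmentation perturbation preserves the study invariants", {
  st <- generate_cohort(cohort_spec(n_symptomatic = 1L, n_asymptomatic = 1L,
                                    seed = 19L))[[1]]
  expect_identical(perturb_segmentation(st, 0, seed = 1), st)
  p1 <- perturb_segmentation(st, 1, seed = 2)
  p2 <- perturb_segmentation(st, 1, seed = 2)
  expect_identical(p1, p2)
  m <- p1$masks
  expect_false(any(m$lumen & !m$outer_wall))
  expect_identical(m$plaque_roi, m$outer_wall & !m$lumen)
  expect_true(any(m$plaque_roi))
  expect_false(identical(m$outer_wall, st$masks$outer_wall))
  # images untouched
  expect_identical(p1$images, st$images)
})

test_that("a jittered second reader gives high but imperfect area agreement", {
  coh <- generate_cohort(cohort_spec(n_symptomatic = 20L, n_asymptomatic = 20L,
                                     seed = 23L))
  a1 <- vapply(coh, function(s) mask_area(s$masks$plaque_roi, 0.3), 0)
  reader2 <- lapply(seq_along(coh), function(i)
    perturb_segmentation(coh[[i]], 1, seed = 100 + i))
  a2 <- vapply(reader2, function(s) mask_area(s$masks$plaque_roi, 0.3), 0)
  icc <- icc_two_way_random_absolute(a1, a2)
  expect_gt(icc, 0.6); expect_lt(icc, 1.0)
})

test_that("cohorts round-trip through nifti files and a manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(n_symptomatic = 1L, n_asymptomatic = 1L,
                                     seed = 29L))
  man <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 2L)
  img <- RNifti::readNifti(man$path_T1[1])
  expect_equal(unclass(img)[, ], coh[[1]]$images$T1$data, ignore_attr = TRUE)
  mk <- RNifti::readNifti(man$path_mask_plaque_roi[1])
  expect_equal(unclass(mk)[, ] == 1, coh[[1]]$masks$plaque_roi,
               ignore_attr = TRUE)
})
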