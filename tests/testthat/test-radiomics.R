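# Radiomic engine: discretisation, feature families, hand-enumerated
# examples and structural invariants.

disc_of <- function(m, n_bins = 2L) {
  structure(list(grid = m, n_bins = as.integer(n_bins),
                 bin_edges = seq(0, n_bins)), class = "disc_roi")
}

test_that("discretisation bins equal-width over the in-mask range", {
  img <- roi_image(matrix(0:31, 4, 8))
  mask <- matrix(TRUE, 4, 8)
  d <- discretise(img, mask, 32)
  expect_identical(sort(unique(as.vector(d$grid))), 1:32)
  expect_equal(d$grid[img$data == 31], 32L)     # max goes to the top bin

  d2 <- discretise(roi_image(matrix(c(0, 10, 20, 30), 2, 2)),
                   matrix(TRUE, 2, 2), 2)
  expect_equal(sort(as.vector(d2$grid)), c(1L, 1L, 2L, 2L))

  dc <- discretise(roi_image(matrix(7, 3, 3)), matrix(TRUE, 3, 3), 8)
  expect_true(all(dc$grid == 1L))

  # partial masks keep outside pixels NA
  mask[1, ] <- FALSE
  dp <- discretise(img, mask, 4)
  expect_true(all(is.na(dp$grid[1, ])))
  expect_error(discretise(img, matrix(FALSE, 4, 8)), "empty")
  expect_error(discretise(img, mask, 1), "n_bins")
})

test_that("first-order statistics match closed forms on simple rois", {
  img <- roi_image(matrix(5, 4, 4))
  d <- discretise(img, matrix(TRUE, 4, 4), 8)
  f <- first_order_features(d, img)
  expect_equal(unname(f["firstorder_Uniformity"]), 1)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["firstorder_StandardDeviation"]), 0)

  # two levels at 50/50
  img2 <- roi_image(matrix(c(0, 0, 1, 1), 2, 2))
  d2 <- discretise(img2, matrix(TRUE, 2, 2), 2)
  f2 <- first_order_features(d2, img2)
  expect_equal(unname(f2["firstorder_Uniformity"]), 0.5)
  expect_equal(unname(f2["firstorder_Entropy"]), 1)
  expect_equal(unname(f2["firstorder_Mean"]), 0.5)
  expect_equal(unname(f2["firstorder_Energy"]), 2)
})

test_that("shape features use physical spacing and the slab convention", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  f <- shape_features(one, 0.3, 2)
  expect_equal(unname(f["shape_Volume"]), 0.3 * 0.3 * 2)
  expect_equal(unname(f["shape_Area"]), 0.09)
  expect_equal(unname(f["shape_Maximum2DDiameterSlice"]), 0)

  line <- matrix(FALSE, 3, 13); line[2, 2:12] <- TRUE
  fl <- shape_features(line, 0.3, 2)
  expect_equal(unname(fl["shape_Maximum2DDiameterSlice"]), 3.0)
  expect_equal(unname(fl["shape_Maximum3DDiameter"]), sqrt(3^2 + 2^2))
  # 11 pixels in one row: column-plane extent is thickness only
  expect_equal(unname(fl["shape_Maximum2DDiameterColumn"]), 2)
  expect_equal(unname(fl["shape_Maximum2DDiameterRow"]), sqrt(3^2 + 2^2))
})

test_that("glcm matches hand enumeration on the 2x2 and checkerboard grids", {
  g <- matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE)
  P <- plaquerad:::glcm_matrix(g, 2L, c(0L, 1L))
  expect_equal(P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2), ignore_attr = TRUE)
  f <- plaquerad:::glcm_features_one(P)
  expect_equal(unname(f["Entropy"]), 1.5)
  expect_equal(unname(f["Contrast"]), 0.5)
  expect_equal(unname(f["Energy"]), 0.375)
  expect_equal(unname(f["MaximumProbability"]), 0.5)

  cb <- matrix(rep(c(1L, 2L), 8), 4, 4)
  cb[, c(2, 4)] <- 3L - cb[, c(2, 4)]
  Pc <- plaquerad:::glcm_matrix(cb, 2L, c(0L, 1L))
  fc <- plaquerad:::glcm_features_one(Pc)
  expect_equal(unname(fc["Contrast"]), 1.0)
  expect_equal(unname(fc["MaximumProbability"]), 0.5)

  # constant roi: single cell
  dcst <- disc_of(matrix(1L, 3, 3), 4)
  fcst <- glcm_features(dcst)
  expect_equal(unname(fcst["glcm_Entropy"]), 0)
  expect_equal(unname(fcst["glcm_Energy"]), 1)
  expect_equal(unname(fcst["glcm_Contrast"]), 0)
  expect_equal(unname(fcst["glcm_Homogeneity"]), 1)
  expect_equal(unname(fcst["glcm_MaximumProbability"]), 1)

  # single pixel: no pair in any direction
  expect_error(glcm_features(disc_of(matrix(1L, 1, 1), 2)), "no valid")
})

test_that("glrlm matches hand enumeration on run fixtures", {
  row3 <- matrix(c(2L, 2L, 2L), 1, 3)
  R <- plaquerad:::glrlm_matrix(row3, 4L, c(0L, 1L))
  f <- plaquerad:::rlm_features_one(R, 3)
  expect_equal(unname(f["RunLengthNonUniformity"]), 1.0)
  expect_equal(unname(f["ShortRunEmphasis"]), 1 / 9)

  alt <- matrix(c(1L, 2L, 1L, 2L), 1, 4)
  Ra <- plaquerad:::glrlm_matrix(alt, 2L, c(0L, 1L))
  fa <- plaquerad:::rlm_features_one(Ra, 4)
  expect_equal(unname(fa["RunLengthNonUniformity"]), 16 / 4)
  expect_equal(unname(fa["RunPercentage"]), 1.0)

  n <- 7
  Rc <- plaquerad:::glrlm_matrix(matrix(1L, 1, n), 2L, c(0L, 1L))
  expect_equal(unname(plaquerad:::rlm_features_one(Rc, n)["ShortRunEmphasis"]),
               1 / n^2)
})

test_that("glszm zones are 8-connected equal-level components", {
  # constant roi: one zone, entropy 0
  f <- glszm_features(disc_of(matrix(2L, 3, 4), 4))
  expect_equal(unname(f["glszm_ZoneEntropy"]), 0)
  expect_equal(unname(f["glszm_ZonePercentage"]), 1 / 12)

  # two disjoint blobs of sizes 3 and 5, same level
  g <- matrix(NA_integer_, 5, 9)
  g[2, 1:3] <- 1L
  g[4:5, 6:7] <- 1L; g[4, 8] <- 1L
  z <- plaquerad:::glszm_zones(g)
  expect_equal(sort(z$size), c(3L, 5L))
  expect_equal(unique(z$level), 1)

  # checkerboard under 8-connectivity: each level's pixels connect along
  # the diagonals into a single zone per level
  cb <- matrix(rep(c(1L, 2L), 8), 4, 4)
  cb[, c(2, 4)] <- 3L - cb[, c(2, 4)]
  zc <- plaquerad:::glszm_zones(cb)
  expect_equal(nrow(zc), 2L)
  expect_equal(sort(zc$size), c(8L, 8L))
})

test_that("texture families agree with brute-force enumerators on random rois", {
  set.seed(99)
  dirs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  for (rep in 1:60) {
    d <- random_disc_roi()
    n_px <- sum(!is.na(d$grid))
    for (off in dirs) {
      P <- plaquerad:::glcm_matrix(d$grid, d$n_bins, off)
      Pb <- brute_glcm(d$grid, d$n_bins, off)
      expect_equal(P, Pb, tolerance = 1e-12)
      if (!is.null(P)) {
        fe <- plaquerad:::glcm_features_one(P)
        fb <- brute_glcm_features(Pb)
        expect_equal(fe[names(fb)], fb, tolerance = 1e-10)
      }
      R <- plaquerad:::glrlm_matrix(d$grid, d$n_bins, off)
      Rb <- brute_glrlm(d$grid, d$n_bins, off)
      expect_equal(dim_pad(R), dim_pad(Rb), tolerance = 1e-12)
      fr <- plaquerad:::rlm_features_one(R, n_px)
      frb <- brute_rlm_features(Rb, n_px)
      expect_equal(fr[names(frb)], frb, tolerance = 1e-10)
    }
    S <- local({
      z <- plaquerad:::glszm_zones(d$grid)
      m <- matrix(0, d$n_bins, max(z$size))
      for (k in seq_len(nrow(z))) m[z$level[k], z$size[k]] <- m[z$level[k], z$size[k]] + 1
      m
    })
    Sb <- brute_glszm(d$grid, d$n_bins)
    expect_equal(dim_pad(S), dim_pad(Sb), tolerance = 1e-12)
    fs <- plaquerad:::szm_features_one(
      plaquerad:::glszm_zones(d$grid), d$n_bins, n_px)
    fsb <- brute_szm_features(Sb, n_px)
    expect_equal(fs[names(fsb)], fsb, tolerance = 1e-10)
  }
})

test_that("texture features are shift-invariant and rotation-consistent", {
  st <- make_test_study(seed = 3, noise = 6)
  mask <- st$masks$plaque_roi
  img <- st$images$T1
  d1 <- discretise(img, mask, 16)
  d2 <- discretise(roi_image(img$data + 250, img$pixel_spacing,
                             img$slice_thickness), mask, 16)
  tex <- function(d) c(glcm_features(d), glrlm_features(d), glszm_features(d))
  expect_equal(tex(d1), tex(d2), tolerance = 1e-12)

  # 90-degree rotation of image + mask leaves direction-averaged features
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE])
  d3 <- discretise(roi_image(rot(img$data)), rot(mask), 16)
  expect_equal(tex(d1), tex(d3), tolerance = 1e-10)
})

test_that("glcm probability matrices are symmetric, normalised and entropy-bounded", {
  set.seed(7)
  for (rep in 1:20) {
    d <- random_disc_roi(max_side = 7, n_bins = 6)
    for (off in list(c(0L, 1L), c(-1L, 1L))) {
      P <- plaquerad:::glcm_matrix(d$grid, d$n_bins, off)
      if (is.null(P)) next
      expect_equal(P, t(P), tolerance = 1e-12)
      expect_equal(sum(P), 1, tolerance = 1e-12)
    }
    ok <- tryCatch({
      f <- glcm_features(d)
      expect_gte(f[["glcm_Entropy"]], 0)
      expect_lte(f[["glcm_Entropy"]], 2 * log2(d$n_bins) + 1e-12)
      TRUE
    }, error = function(e) TRUE)   # single-pixel rois legitimately error
    expect_true(ok)
  }
})

test_that("extract_features emits the fixed 98-name catalogue per sequence", {
  st <- make_test_study(seed = 11, noise = 4)
  fv <- extract_features(st)
  expect_named(fv, c("T1", "T2", "CE_T1"))
  for (sq in names(fv)) {
    expect_identical(names(fv[[sq]]), feature_catalogue())
    expect_length(fv[[sq]], 98L)
    expect_true(all(is.finite(fv[[sq]])))
  }
  # zero-noise study: constant annulus, zero texture entropy
  st0 <- make_test_study(seed = 1, noise = 0)
  fv0 <- extract_features(st0, sequences = "T1")
  expect_equal(unname(fv0$T1["glcm_Entropy"]), 0)
  expect_equal(unname(fv0$T1["firstorder_Entropy"]), 0)
})
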