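# 2D radiomic feature engine: first-order, shape, GLCM, GLRLM and GLSZM
# families over a discretised plaque ROI. Grey-level indices i, j are 1-based
# bin labels throughout; logarithms are base 2 with 0*log(0) == 0.

log2z <- function(p) {
  out <- p
  pos <- p > 0
  out[pos] <- log2(p[pos])
  out[!pos] <- 0
  out
}

# The four in-plane directions used for co-occurrence and run-length
# statistics, as (row, column) offsets: 0, 45, 90 and 135 degrees.
texture_directions <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Radiomic feature catalogue
#'
#' The engine emits a fixed, ordered catalogue of 98 named features per
#' sequence: 14 first-order intensity statistics, 18 histogram/percentile
#' auxiliaries, 10 shape descriptors and 24 + 16 + 16 texture features from
#' the grey-level co-occurrence, run-length and size-zone matrices.
#'
#' @return Character vector of feature names in catalogue order.
#' @export
feature_catalogue <- function() {
  c(
    paste0("firstorder_", c(
      "Maximum", "Minimum", "Mean", "Median", "Range", "StandardDeviation",
      "Variance", "MeanAbsoluteDeviation", "RootMeanSquared", "Energy",
      "Skewness", "Kurtosis", "Uniformity", "Entropy",
      # histogram / percentile auxiliaries
      "Percentile5", "Percentile10", "Percentile25", "Percentile75",
      "Percentile90", "Percentile95", "InterquartileRange", "DecileRange",
      "RobustMeanAbsoluteDeviation", "MedianAbsoluteDeviation", "TotalEnergy",
      "CoefficientOfVariation", "QuartileDispersion", "BowleySkewness",
      "TrimmedMean10", "HistogramMode", "HistogramModeProbability",
      "HistogramOccupiedLevels")),
    paste0("shape_", c(
      "Area", "Perimeter", "Volume", "SurfaceArea", "Maximum2DDiameterSlice",
      "Maximum3DDiameter", "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
      "Sphericity", "Elongation")),
    paste0("glcm_", c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Dissimilarity", "Energy",
      "Entropy", "Homogeneity", "Idm", "Idmn", "Idn", "InverseVariance",
      "Imc1", "Imc2", "JointAverage", "JointVariance", "MaximumProbability",
      "SumAverage", "SumEntropy")),
    paste0("glrlm_", c(
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")),
    paste0("glszm_", c(
      "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
  )
}

## ---------------------------------------------------------------------------
## first-order

#' First-order intensity features
#'
#' Moments, percentiles and energy statistics on the raw in-mask intensities,
#' plus uniformity (sum of squared bin probabilities) and entropy
#' (base-2 Shannon) on the discretised histogram. Spread statistics use the
#' population convention (denominator n).
#'
#' @param disc A [discretise]d ROI.
#' @param roi The raw [roi_image] the discretisation came from.
#' @return Named numeric vector (`firstorder_*` entries of the catalogue).
#' @export
first_order_features <- function(disc, roi) {
  data <- if (inherits(roi, "roi_image")) roi$data else roi
  x <- data[!is.na(disc$grid)]
  n <- length(x)
  mu <- mean(x)
  va <- sum((x - mu)^2) / n
  sdv <- sqrt(va)
  q <- unname(stats::quantile(x, c(.05, .1, .25, .5, .75, .9, .95), type = 7))
  p1090 <- x[x >= q[2] & x <= q[6]]
  hist_p <- tabulate(disc$grid[!is.na(disc$grid)], nbins = disc$n_bins) / n
  vol_px <- prod(attr_spacing(roi)) # mm^3 per voxel
  skew <- if (sdv > 0) (sum((x - mu)^3) / n) / sdv^3 else 0
  kurt <- if (sdv > 0) (sum((x - mu)^4) / n) / sdv^4 else 0
  mode_bin <- which.max(hist_p)
  out <- c(
    Maximum = max(x), Minimum = min(x), Mean = mu, Median = q[4],
    Range = max(x) - min(x), StandardDeviation = sdv, Variance = va,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RootMeanSquared = sqrt(mean(x^2)), Energy = sum(x^2),
    Skewness = skew, Kurtosis = kurt,
    Uniformity = sum(hist_p^2), Entropy = -sum(hist_p * log2z(hist_p)),
    Percentile5 = q[1], Percentile10 = q[2], Percentile25 = q[3],
    Percentile75 = q[5], Percentile90 = q[6], Percentile95 = q[7],
    InterquartileRange = q[5] - q[3], DecileRange = q[6] - q[2],
    RobustMeanAbsoluteDeviation = mean(abs(p1090 - mean(p1090))),
    MedianAbsoluteDeviation = stats::median(abs(x - q[4])),
    TotalEnergy = vol_px * sum(x^2),
    CoefficientOfVariation = if (mu != 0) sdv / mu else 0,
    QuartileDispersion = if ((q[5] + q[3]) != 0) (q[5] - q[3]) / (q[5] + q[3]) else 0,
    BowleySkewness = if ((q[5] - q[3]) > 0) (q[5] + q[3] - 2 * q[4]) / (q[5] - q[3]) else 0,
    TrimmedMean10 = mean(x, trim = 0.1),
    HistogramMode = as.numeric(mode_bin),
    HistogramModeProbability = hist_p[mode_bin],
    HistogramOccupiedLevels = sum(hist_p > 0)
  )
  stats::setNames(out, paste0("firstorder_", names(out)))
}

attr_spacing <- function(roi) {
  if (inherits(roi, "roi_image")) {
    c(roi$pixel_spacing, roi$slice_thickness)
  } else {
    c(1, 1, 1)
  }
}

## ---------------------------------------------------------------------------
## shape

#' Shape features of a 2D mask treated as a one-voxel-thick volume
#'
#' Areas come from pixel counting (pixel count times pixel area, matching
#' manual raster segmentation), perimeter from exposed pixel edges, and the
#' volume/surface statistics treat the slice as a slab one slice-thickness
#' deep. Maximum diameters are maximal pairwise pixel-centre distances: the
#' in-plane one for `Maximum2DDiameterSlice`, with the slice-thickness offset
#' added for the 3D and column/row-plane variants.
#'
#' @param mask Logical matrix.
#' @param pixel_spacing In-plane pixel size in mm (length 2 or scalar).
#' @param slice_thickness Slice thickness in mm.
#' @return Named numeric vector (`shape_*` entries of the catalogue).
#' @export
shape_features <- function(mask, pixel_spacing = 0.3, slice_thickness = 2) {
  check_mask(mask)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  sp_r <- pixel_spacing[1]; sp_c <- pixel_spacing[2]
  idx <- which(mask, arr.ind = TRUE)
  n_px <- nrow(idx)
  area <- n_px * sp_r * sp_c
  volume <- area * slice_thickness

  # exposed 4-neighbour edges; horizontal edges have length sp_c, vertical sp_r
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  core <- pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  up    <- core & !pad[1:nrow(mask), 2:(ncol(mask) + 1L)]
  down  <- core & !pad[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)]
  left  <- core & !pad[2:(nrow(mask) + 1L), 1:ncol(mask)]
  right <- core & !pad[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  perimeter <- (sum(up) + sum(down)) * sp_c + (sum(left) + sum(right)) * sp_r
  surface <- 2 * area + perimeter * slice_thickness

  # physical pixel-centre coordinates; pairwise maxima via the convex hull
  ry <- idx[, 1] * sp_r; cx <- idx[, 2] * sp_c
  if (n_px == 1L) {
    d2max <- 0
  } else {
    pts <- cbind(ry, cx)
    hull <- unique(pts[grDevices::chull(pts), , drop = FALSE])
    d2max <- sqrt(max(as.matrix(stats::dist(hull))^2))
  }
  row_ext <- diff(range(ry)); col_ext <- diff(range(cx))
  d3max <- sqrt(d2max^2 + slice_thickness^2)
  d_col <- sqrt(row_ext^2 + slice_thickness^2)
  d_row <- sqrt(col_ext^2 + slice_thickness^2)
  sphericity <- (36 * pi * volume^2)^(1 / 3) / surface
  if (n_px > 1L) {
    ev <- eigen(stats::cov(cbind(ry, cx)), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
    elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  } else {
    elongation <- 0
  }
  out <- c(Area = area, Perimeter = perimeter, Volume = volume,
           SurfaceArea = surface, Maximum2DDiameterSlice = d2max,
           Maximum3DDiameter = d3max, Maximum2DDiameterColumn = d_col,
           Maximum2DDiameterRow = d_row, Sphericity = sphericity,
           Elongation = elongation)
  stats::setNames(out, paste0("shape_", names(out)))
}

## ---------------------------------------------------------------------------
## GLCM

# Symmetric normalised co-occurrence matrix for one (row, col) offset.
# Pairs with either pixel outside the mask are discarded. Returns NULL when
# the direction has no valid pair.
glcm_matrix <- function(grid, n_bins, offset) {
  nr <- nrow(grid); nc <- ncol(grid)
  dr <- offset[1]; dc <- offset[2]
  if (max(1L, 1L - dr) > min(nr, nr - dr) ||
      max(1L, 1L - dc) > min(nc, nc - dc)) {
    return(NULL)                         # offset exceeds the grid
  }
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- grid[r1, c1, drop = FALSE]
  b <- grid[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  i <- a[ok]; j <- b[ok]
  tab <- matrix(tabulate(i + (j - 1L) * n_bins, nbins = n_bins * n_bins),
                n_bins, n_bins)
  counts <- tab + t(tab)                 # symmetric
  counts / sum(counts)
}

glcm_features_one <- function(P) {
  n <- nrow(P)
  i <- matrix(1:n, n, n); j <- t(i)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  # diagonal (difference) and cross-diagonal (sum) probabilities
  k_diff <- 0:(n - 1)
  p_diff <- as.vector(rowsum(as.vector(P), group = as.vector(abs(i - j))))
  k_sum <- 2:(2 * n)
  p_sum <- as.vector(rowsum(as.vector(P), group = as.vector(i + j)))
  ent <- -sum(P * log2z(P))
  hx <- -sum(pi_ * log2z(pi_))
  hxy1 <- -sum(P * log2z(outer(pi_, pj_)))
  hxy2 <- -sum(outer(pi_, pj_) * log2z(outer(pi_, pj_)))
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- max(0, 1 - 2^(-2 * (hxy2 - ent)))
  imc2 <- sqrt(imc2)
  da <- sum(k_diff * p_diff)
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mu_i - mu_j)^4 * P),
    ClusterShade = sum((i + j - mu_i - mu_j)^3 * P),
    ClusterTendency = sum((i + j - mu_i - mu_j)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sd_i > 0 && sd_j > 0)
      (sum(i * j * P) - mu_i * mu_j) / (sd_i * sd_j) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff * log2z(p_diff)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Dissimilarity = sum(abs(i - j) * P),
    Energy = sum(P^2),
    Entropy = ent,
    Homogeneity = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / n^2)),
    Idn = sum(P / (1 + abs(i - j) / n)),
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    Imc1 = imc1,
    Imc2 = imc2,
    JointAverage = mu_i,
    JointVariance = sum((i - mu_i)^2 * P),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum * log2z(p_sum))
  )
}

#' Grey-level co-occurrence matrix features
#'
#' Builds a symmetric, normalised GLCM for each of the four in-plane
#' directions at the given pixel distance (pairs crossing the mask boundary
#' are discarded) and averages the per-direction features. Directions with no
#' valid pixel pair are dropped from the average; an ROI with no valid pair
#' in any direction is an error.
#'
#' @param disc A [discretise]d ROI.
#' @param distance Pair offset in pixels (default 1).
#' @return Named numeric vector (`glcm_*` entries of the catalogue).
#' @export
glcm_features <- function(disc, distance = 1L) {
  mats <- lapply(texture_directions(), function(d)
    glcm_matrix(disc$grid, disc$n_bins, d * as.integer(distance)))
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) == 0L) {
    stop("no valid pixel pair in any direction; texture undefined", call. = FALSE)
  }
  per_dir <- vapply(mats, glcm_features_one, numeric(24L))
  avg <- rowMeans(per_dir)
  stats::setNames(avg, paste0("glcm_", names(avg)))
}

## ---------------------------------------------------------------------------
## GLRLM

# Extract the label sequences along each line of a direction; NA (out of
# mask) breaks runs.
direction_lines <- function(grid, offset) {
  nr <- nrow(grid); nc <- ncol(grid)
  if (identical(abs(offset), c(0L, 1L))) {
    lapply(seq_len(nr), function(r) grid[r, ])
  } else if (identical(abs(offset), c(1L, 0L))) {
    lapply(seq_len(nc), function(c) grid[, c])
  } else {
    ri <- matrix(seq_len(nr), nr, nc)
    ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    key <- if (offset[1] * offset[2] < 0) ri + ci else ri - ci   # anti- / main diagonal
    split(grid, key)
  }
}

glrlm_matrix <- function(grid, n_bins, offset) {
  lines <- direction_lines(grid, offset)
  lev <- integer(0); len <- integer(0)
  for (v in lines) {
    r <- rle(as.vector(v))
    keep <- !is.na(r$values)
    lev <- c(lev, r$values[keep])
    len <- c(len, r$lengths[keep])
  }
  if (length(lev) == 0L) return(NULL)
  max_len <- max(len)
  R <- matrix(0, n_bins, max_len)
  for (k in seq_along(lev)) R[lev[k], len[k]] <- R[lev[k], len[k]] + 1
  R
}

rlm_features_one <- function(R, n_px) {
  n_runs <- sum(R)
  i <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  p <- R / n_runs
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  c(
    ShortRunEmphasis = sum(R / j^2) / n_runs,
    LongRunEmphasis = sum(R * j^2) / n_runs,
    GrayLevelNonUniformity = sum(rowSums(R)^2) / n_runs,
    GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / n_runs^2,
    RunLengthNonUniformity = sum(colSums(R)^2) / n_runs,
    RunLengthNonUniformityNormalized = sum(colSums(R)^2) / n_runs^2,
    RunPercentage = n_runs / n_px,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (j - mu_j)^2),
    RunEntropy = -sum(p * log2z(p)),
    LowGrayLevelRunEmphasis = sum(R / i^2) / n_runs,
    HighGrayLevelRunEmphasis = sum(R * i^2) / n_runs,
    ShortRunLowGrayLevelEmphasis = sum(R / (i^2 * j^2)) / n_runs,
    ShortRunHighGrayLevelEmphasis = sum(R * i^2 / j^2) / n_runs,
    LongRunLowGrayLevelEmphasis = sum(R * j^2 / i^2) / n_runs,
    LongRunHighGrayLevelEmphasis = sum(R * i^2 * j^2) / n_runs
  )
}

#' Grey-level run-length matrix features
#'
#' Runs of equal grey level are collected along each of the four in-plane
#' directions (runs break at the mask boundary); the standard run-emphasis
#' and non-uniformity statistics are computed per direction and averaged.
#'
#' @param disc A [discretise]d ROI.
#' @return Named numeric vector (`glrlm_*` entries of the catalogue).
#' @export
glrlm_features <- function(disc) {
  n_px <- sum(!is.na(disc$grid))
  mats <- lapply(texture_directions(), function(d)
    glrlm_matrix(disc$grid, disc$n_bins, d))
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) == 0L) {
    stop("no run in any direction; texture undefined", call. = FALSE)
  }
  per_dir <- vapply(mats, rlm_features_one, numeric(16L), n_px = n_px)
  avg <- rowMeans(per_dir)
  stats::setNames(avg, paste0("glrlm_", names(avg)))
}

## ---------------------------------------------------------------------------
## GLSZM

# Zone sizes per grey level: 8-connected components of equal-label pixels.
glszm_zones <- function(grid) {
  idx <- which(!is.na(grid))
  nr <- nrow(grid)
  pos <- data.frame(r = ((idx - 1L) %% nr) + 1L,
                    c = ((idx - 1L) %/% nr) + 1L,
                    lab = grid[idx], id = seq_along(idx))
  key <- matrix(NA_integer_, nr, ncol(grid))
  key[idx] <- pos$id
  edges <- NULL
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- pos$r + off[1]; c2 <- pos$c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(grid)
    nb <- rep(NA_integer_, nrow(pos))
    nb[ok] <- key[cbind(r2[ok], c2[ok])]
    same <- !is.na(nb)
    same[same] <- pos$lab[which(same)] == pos$lab[nb[which(same)]]
    edges <- rbind(edges, cbind(pos$id[same], nb[same]))
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    comp <- seq_len(nrow(pos))
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nrow(pos) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(nrow(pos))]
  }
  zones <- data.frame(level = tapply(pos$lab, comp, function(z) z[1]),
                      size = as.integer(table(comp)))
  zones
}

szm_features_one <- function(zones, n_bins, n_px) {
  max_s <- max(zones$size)
  S <- matrix(0, n_bins, max_s)
  for (k in seq_len(nrow(zones))) {
    S[zones$level[k], zones$size[k]] <- S[zones$level[k], zones$size[k]] + 1
  }
  n_z <- sum(S)
  i <- matrix(seq_len(n_bins), n_bins, max_s)
  s <- matrix(seq_len(max_s), n_bins, max_s, byrow = TRUE)
  p <- S / n_z
  mu_i <- sum(p * i); mu_s <- sum(p * s)
  c(
    SmallAreaEmphasis = sum(S / s^2) / n_z,
    LargeAreaEmphasis = sum(S * s^2) / n_z,
    GrayLevelNonUniformity = sum(rowSums(S)^2) / n_z,
    GrayLevelNonUniformityNormalized = sum(rowSums(S)^2) / n_z^2,
    SizeZoneNonUniformity = sum(colSums(S)^2) / n_z,
    SizeZoneNonUniformityNormalized = sum(colSums(S)^2) / n_z^2,
    ZonePercentage = n_z / n_px,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (s - mu_s)^2),
    ZoneEntropy = -sum(p * log2z(p)),
    LowGrayLevelZoneEmphasis = sum(S / i^2) / n_z,
    HighGrayLevelZoneEmphasis = sum(S * i^2) / n_z,
    SmallAreaLowGrayLevelEmphasis = sum(S / (i^2 * s^2)) / n_z,
    SmallAreaHighGrayLevelEmphasis = sum(S * i^2 / s^2) / n_z,
    LargeAreaLowGrayLevelEmphasis = sum(S * s^2 / i^2) / n_z,
    LargeAreaHighGrayLevelEmphasis = sum(S * i^2 * s^2) / n_z
  )
}

#' Grey-level size-zone matrix features
#'
#' Zones are 8-connected components of equal grey level; the size-zone
#' analogues of the run-length statistics are computed from the (level x
#' zone-size) histogram. The GLSZM has no directionality, so no averaging
#' is involved.
#'
#' @param disc A [discretise]d ROI.
#' @return Named numeric vector (`glszm_*` entries of the catalogue).
#' @export
glszm_features <- function(disc) {
  n_px <- sum(!is.na(disc$grid))
  zones <- glszm_zones(disc$grid)
  out <- szm_features_one(zones, disc$n_bins, n_px)
  stats::setNames(out, paste0("glszm_", names(out)))
}

## ---------------------------------------------------------------------------
## full extraction

#' Extract the full radiomic feature catalogue from one plaque study
#'
#' Runs the discretisation and all five feature families on the plaque ROI of
#' each requested sequence. Shape features depend only on the mask and are
#' computed once, then replicated per sequence. Output order follows
#' [feature_catalogue()].
#'
#' @param study A `plaque_study` (see [generate_cohort()]), or any list with
#'   `images` (named list of [roi_image]) and `masks$plaque_roi`.
#' @param sequences Which sequences to extract (default all present).
#' @param n_bins Grey levels for discretisation.
#' @param distance GLCM pair distance in pixels.
#' @return Named list (one entry per sequence) of named numeric vectors, each
#'   the full 98-feature catalogue.
#' @export
extract_features <- function(study, sequences = names(study$images),
                             n_bins = 32L, distance = 1L) {
  mask <- study$masks$plaque_roi
  check_mask(mask)
  img1 <- study$images[[sequences[1]]]
  shp <- shape_features(mask, img1$pixel_spacing, img1$slice_thickness)
  out <- lapply(sequences, function(sq) {
    img <- study$images[[sq]]
    if (is.null(img)) stop("sequence not present: ", sq, call. = FALSE)
    disc <- discretise(img, mask, n_bins)
    fv <- c(first_order_features(disc, img), shp,
            glcm_features(disc, distance), glrlm_features(disc),
            glszm_features(disc))
    fv <- fv[feature_catalogue()]
    if (anyNA(fv)) stop("non-finite feature on sequence ", sq, call. = FALSE)
    fv
  })
  stats::setNames(out, sequences)
}

#' Extract features for every study in a cohort as a wide table
#'
#' @param cohort List of plaque studies.
#' @param sequences Sequences to extract.
#' @param n_bins,distance Passed to [extract_features()].
#' @return A data.frame with `patient_id`, `label`, and one column per
#'   sequence-prefixed feature (e.g. `T1_glcm_Entropy`).
#' @export
cohort_features <- function(cohort, sequences = c("T1", "T2", "CE_T1"),
                            n_bins = 32L, distance = 1L) {
  rows <- lapply(cohort, function(st) {
    fv <- extract_features(st, sequences, n_bins, distance)
    vals <- unlist(lapply(sequences, function(sq)
      stats::setNames(fv[[sq]], paste0(sq, "_", names(fv[[sq]])))))
    c(vals)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(
    data.frame(patient_id = vapply(cohort, function(s) s$patient_id, ""),
               label = vapply(cohort, function(s) s$label, ""),
               stringsAsFactors = FALSE),
    tab)
  rownames(tab) <- NULL
  tab
}
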