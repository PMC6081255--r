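# Conventional ("traditional") plaque measurements from images and masks:
# plaque burden, enhancement ratio, intraplaque haemorrhage, minimal luminal
# area and WASID-style stenosis.

#' Plaque burden
#'
#' Fraction of the vessel cross-section occupied by wall/plaque,
#' (1 - lumen area / outer area) x 100.
#'
#' @param lumen_area,outer_area Areas in mm^2; `0 <= lumen_area <= outer_area`,
#'   `outer_area > 0`.
#' @return Percent in \[0, 100\].
#' @export
plaque_burden <- function(lumen_area, outer_area) {
  if (any(outer_area <= 0)) stop("outer_area must be positive", call. = FALSE)
  if (any(lumen_area < 0) || any(lumen_area > outer_area)) {
    stop("lumen_area must lie in [0, outer_area]", call. = FALSE)
  }
  (1 - lumen_area / outer_area) * 100
}

#' Contrast enhancement ratio
#'
#' Relative increase of plaque signal after gadolinium, normalised by a
#' grey-matter reference region imaged pre and post contrast:
#' ((plaque_post/gm_post) / (plaque_pre/gm_pre) - 1) x 100. The grey-matter
#' normalisation makes the ratio invariant to independent global rescaling of
#' the pre- and post-contrast images.
#'
#' @param plaque_pre,gm_pre,plaque_post,gm_post Mean ROI signal intensities,
#'   all positive.
#' @return Percent (may be negative if plaque signal drops).
#' @export
enhancement_ratio <- function(plaque_pre, gm_pre, plaque_post, gm_post) {
  vals <- c(plaque_pre, gm_pre, plaque_post, gm_post)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ROI intensities must be positive", call. = FALSE)
  }
  ((plaque_post / gm_post) / (plaque_pre / gm_pre) - 1) * 100
}

#' Detect intraplaque haemorrhage on pre-contrast T1
#'
#' IPH is called when a sufficiently large 8-connected component of plaque
#' pixels is hyperintense relative to a reference muscle region: every pixel
#' of the component must exceed `threshold` times the muscle mean (the >150%
#' rule by default). Requiring a component of at least `min_component_px`
#' pixels keeps the call robust to single-pixel noise.
#'
#' @param t1 A [roi_image] (or matrix): pre-contrast T1 intensities.
#' @param plaque_mask Logical matrix, non-empty.
#' @param muscle_mean Mean signal of the reference muscle ROI (> 0).
#' @param min_component_px Minimum hyperintense component size (default 3).
#' @param threshold Intensity ratio defining hyperintensity (default 1.5).
#' @return `TRUE` if IPH is present.
#' @export
detect_iph <- function(t1, plaque_mask, muscle_mean, min_component_px = 3L,
                       threshold = 1.5) {
  data <- if (inherits(t1, "roi_image")) t1$data else t1
  check_mask(plaque_mask, data)
  if (!is.finite(muscle_mean) || muscle_mean <= 0) {
    stop("muscle_mean must be positive", call. = FALSE)
  }
  hyper <- plaque_mask & (data > threshold * muscle_mean)
  if (!any(hyper)) return(FALSE)
  grid <- matrix(NA_integer_, nrow(data), ncol(data))
  grid[hyper] <- 1L
  zones <- glszm_zones(grid)
  max(zones$size) >= min_component_px
}

#' Minimal luminal area
#'
#' Smallest lumen cross-sectional area along the lesion.
#'
#' @param lumen_areas Non-empty vector of per-slice lumen areas (mm^2, >= 0).
#' @return mm^2.
#' @export
minimal_luminal_area <- function(lumen_areas) {
  if (length(lumen_areas) == 0L) stop("no lumen areas supplied", call. = FALSE)
  if (any(lumen_areas < 0)) stop("lumen areas must be non-negative", call. = FALSE)
  min(lumen_areas)
}

#' Degree of stenosis (diameter-based)
#'
#' WASID-style percent stenosis from the most stenotic lumen area and a
#' reference (normal-appearing) lumen area, converting areas to equivalent
#' circular diameters d = 2 sqrt(area/pi): (1 - d_sten/d_ref) x 100.
#'
#' @param lumen_area_at_mla Lumen area at the most stenotic site (mm^2, >= 0).
#' @param reference_lumen_area Reference lumen area (mm^2, > 0).
#' @return Percent, <= 100.
#' @export
stenosis_degree <- function(lumen_area_at_mla, reference_lumen_area) {
  if (reference_lumen_area <= 0) stop("reference lumen area must be positive", call. = FALSE)
  if (lumen_area_at_mla < 0) stop("lumen area must be non-negative", call. = FALSE)
  (1 - sqrt(lumen_area_at_mla / reference_lumen_area)) * 100
}

#' Mask area in mm^2
#'
#' Pixel count times pixel area.
#'
#' @param mask Logical matrix.
#' @param pixel_spacing In-plane pixel size in mm (length 2 or scalar).
#' @return mm^2.
#' @export
mask_area <- function(mask, pixel_spacing = 0.3) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  sum(mask) * pixel_spacing[1] * pixel_spacing[2]
}

#' Conventional plaque metrics for one study
#'
#' Computes the full traditional measurement set from a plaque study's images
#' and masks: lumen/outer/plaque areas, plaque burden, MLA (the single
#' analysed slice is the maximum-plaque-area slice, so its lumen area is the
#' MLA), stenosis, IPH and enhancement ratio.
#'
#' @param study A `plaque_study`.
#' @param min_component_px Passed to [detect_iph()].
#' @return One-row data.frame of named metrics.
#' @export
conventional_metrics <- function(study, min_component_px = 3L) {
  sp <- study$images$T1$pixel_spacing
  lumen <- mask_area(study$masks$lumen, sp)
  outer <- mask_area(study$masks$outer_wall, sp)
  plaque <- mask_area(study$masks$plaque_roi, sp)
  t1 <- study$images$T1; ce <- study$images$CE_T1
  muscle_mean <- mean(t1$data[study$masks$muscle_ref])
  gm_pre <- mean(t1$data[study$masks$grey_matter_ref])
  gm_post <- mean(ce$data[study$masks$grey_matter_ref])
  pl_pre <- mean(t1$data[study$masks$plaque_roi])
  pl_post <- mean(ce$data[study$masks$plaque_roi])
  ref_area <- if (!is.null(study$reference_lumen_area)) {
    study$reference_lumen_area
  } else {
    outer  # fall back: healthy lumen approximated by the outer wall area
  }
  data.frame(
    patient_id = study$patient_id,
    label = study$label,
    lumen_area = lumen,
    outer_area = outer,
    plaque_area = plaque,
    plaque_burden = plaque_burden(lumen, outer),
    mla = minimal_luminal_area(lumen),
    stenosis_percent = stenosis_degree(lumen, ref_area),
    iph = detect_iph(t1, study$masks$plaque_roi, muscle_mean,
                     min_component_px = min_component_px),
    enhancement_ratio = enhancement_ratio(pl_pre, gm_pre, pl_post, gm_post),
    stringsAsFactors = FALSE
  )
}

#' Conventional metrics for a whole cohort
#'
#' @param cohort List of plaque studies.
#' @param ... Passed to [conventional_metrics()].
#' @return data.frame, one row per study, with clinical covariates appended.
#' @export
cohort_conventional <- function(cohort, ...) {
  rows <- lapply(cohort, conventional_metrics, ...)
  tab <- do.call(rbind, rows)
  cov <- do.call(rbind, lapply(cohort, function(s)
    as.data.frame(s$covariates, stringsAsFactors = FALSE)))
  cbind(tab, cov)
}
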