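# Synthetic plaque-image cohort generator. Emulates the cohort structure the
# analysis assumes: 61 acute/sub-acute symptomatic vs 35 asymptomatic basilar
# plaques, group-specific IPH prevalence (19/61 vs 1/35), minimal luminal
# area, enhancement ratio, plaque burden and texture heterogeneity, plus the
# clinical covariate mix. One 64 x 64 cross-sectional slice per patient at
# 0.3 mm in-plane spacing and 2 mm thickness (the analysed
# maximum-plaque-area slice), in three contrasts (T1, T2, CE-T1).

#' Specification of a synthetic plaque cohort
#'
#' All distributional defaults encode the study conditions of the cohort the
#' analysis targets: group sizes, per-group IPH prevalence, MLA and
#' enhancement-ratio means/SDs, plaque burden, stenosis, covariate
#' frequencies, and a per-group texture-heterogeneity scale (the knob that
#' drives grey-level texture differences between groups; dimensionless,
#' calibrated so T1 GLCM entropy lands near 5.8 vs 5.4 at 32 grey levels).
#'
#' @param n_symptomatic,n_asymptomatic Group sizes (> 0).
#' @param iph_prevalence Probability of an IPH blob, `c(symptomatic, asymptomatic)`.
#' @param mla_mean_sd List of `c(mean, sd)` mm^2 per group.
#' @param enhancement_mean_sd List of `c(mean, sd)` percent per group.
#' @param plaque_area_mean_sd List of `c(mean, sd)` mm^2 of wall/plaque
#'   cross-sectional area per group (the single-slice analogue of the group
#'   wall-volume statistics); plaque burden emerges from area + MLA.
#' @param stenosis_mean_sd List of `c(mean, sd)` percent per group.
#' @param texture_heterogeneity Noise-scale pair `c(symptomatic, asymptomatic)`.
#' @param t2_texture_heterogeneity Scalar noise scale shared by both groups on
#'   T2 (the sequence carries no group texture signal).
#' @param covariate_probs Named list of `c(p_sym, p_asym)` Bernoulli
#'   probabilities for sex (male), diabetes, hypertension, hyperlipidaemia,
#'   smoking.
#' @param age_mean_sd List of `c(mean, sd)` years per group.
#' @param grid_size Image grid side in pixels.
#' @param pixel_spacing In-plane pixel size, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param seed Integer seed; fixes the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_symptomatic = 61L, n_asymptomatic = 35L,
                        iph_prevalence = c(19 / 61, 1 / 35),
                        mla_mean_sd = list(symptomatic = c(3.78, 2.80),
                                           asymptomatic = c(2.39, 1.46)),
                        enhancement_mean_sd = list(symptomatic = c(24.20, 29.46),
                                                   asymptomatic = c(3.38, 21.91)),
                        plaque_area_mean_sd = list(symptomatic = c(20.08, 12.00),
                                                   asymptomatic = c(13.70, 7.32)),
                        stenosis_mean_sd = list(symptomatic = c(53.69, 15.19),
                                                asymptomatic = c(53.76, 16.73)),
                        texture_heterogeneity = c(0.75, 0.5),
                        t2_texture_heterogeneity = 0.65,
                        covariate_probs = list(
                          sex_male = c(46 / 61, 18 / 35),
                          diabetes = c(23 / 61, 11 / 35),
                          hypertension = c(48 / 61, 30 / 35),
                          hyperlipidaemia = c(23 / 61, 11 / 35),
                          smoking = c(23 / 61, 4 / 35)),
                        age_mean_sd = list(symptomatic = c(61.68, 10.75),
                                           asymptomatic = c(62.14, 8.92)),
                        grid_size = 64L, pixel_spacing = 0.3,
                        slice_thickness = 2, seed = 1L) {
  stopifnot(n_symptomatic > 0, n_asymptomatic > 0)
  if (any(iph_prevalence < 0) || any(iph_prevalence > 1)) {
    stop("iph_prevalence must be probabilities", call. = FALSE)
  }
  sds <- c(mla_mean_sd$symptomatic[2], mla_mean_sd$asymptomatic[2],
           enhancement_mean_sd$symptomatic[2], enhancement_mean_sd$asymptomatic[2])
  if (any(sds < 0)) stop("SDs must be non-negative", call. = FALSE)
  if (pixel_spacing <= 0 || slice_thickness <= 0) {
    stop("spacing must be positive", call. = FALSE)
  }
  if (any(texture_heterogeneity < 0) || t2_texture_heterogeneity < 0) {
    stop("texture heterogeneity must be non-negative", call. = FALSE)
  }
  structure(list(
    n_symptomatic = as.integer(n_symptomatic),
    n_asymptomatic = as.integer(n_asymptomatic),
    iph_prevalence = iph_prevalence,
    mla_mean_sd = mla_mean_sd,
    enhancement_mean_sd = enhancement_mean_sd,
    plaque_area_mean_sd = plaque_area_mean_sd,
    stenosis_mean_sd = stenosis_mean_sd,
    texture_heterogeneity = texture_heterogeneity,
    t2_texture_heterogeneity = t2_texture_heterogeneity,
    covariate_probs = covariate_probs,
    age_mean_sd = age_mean_sd,
    grid_size = as.integer(grid_size),
    pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness,
    seed = as.integer(seed)), class = "cohort_spec")
}

# Evaluate `expr` under `seed` without leaking state into the caller's RNG.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Mean of a normal truncated to [lower, upper]
tn_mean <- function(m, sd, lower, upper) {
  a <- (lower - m) / sd; b <- (upper - m) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  m + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Truncated-normal draw whose *post-truncation* mean equals `target`:
# the location parameter is shifted to undo the truncation bias, so group
# means of bounded quantities (e.g. MLA > 0) stay on their targets.
rtrunc_norm_meanadj <- function(n, target, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(target, n))
  m <- stats::uniroot(function(m) tn_mean(m, sd, lower, upper) - target,
                      interval = c(target - 6 * sd, target + 6 * sd),
                      extendInt = "upX")$root
  rtrunc_norm(n, m, sd, lower, upper)
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

# White noise smoothed with a small separable Gaussian kernel, then
# standardised to unit variance; the noise *amplitude* is applied by callers.
smooth_noise <- function(n, sigma = 0.8, radius = NULL) {
  if (is.null(radius)) radius <- min(8L, max(1L, ceiling(3 * sigma)))
  z <- matrix(stats::rnorm(n * n), n, n)
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  pad <- radius
  zp <- matrix(0, n + 2 * pad, n + 2 * pad)
  zp[(pad + 1):(pad + n), (pad + 1):(pad + n)] <- z
  # rows then columns
  out <- matrix(0, n + 2 * pad, n + 2 * pad)
  for (d in -radius:radius) {
    out[, (pad + 1):(pad + n)] <- out[, (pad + 1):(pad + n)] +
      k[d + radius + 1] * zp[, (pad + 1 + d):(pad + n + d)]
  }
  out2 <- matrix(0, n, n)
  for (d in -radius:radius) {
    out2 <- out2 + k[d + radius + 1] * out[(pad + 1 + d):(pad + n + d), (pad + 1):(pad + n)]
  }
  out2 / stats::sd(out2)
}

# Pixelated concentric ellipse pair: TRUE where the implicit ellipse value
# <= 1. Areas are controlled through the semi-axes.
ellipse_mask <- function(n, centre, semi_axes, theta = 0) {
  r <- matrix(seq_len(n), n, n) - centre[1]
  c <- matrix(seq_len(n), n, n, byrow = TRUE) - centre[2]
  u <- r * cos(theta) + c * sin(theta)
  v <- -r * sin(theta) + c * cos(theta)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

disc_mask <- function(n, centre, radius_px) {
  r <- matrix(seq_len(n), n, n) - centre[1]
  c <- matrix(seq_len(n), n, n, byrow = TRUE) - centre[2]
  r^2 + c^2 <= radius_px^2
}

#' Render one synthetic plaque cross-section
#'
#' Builds the intensity image for one contrast: dark lumen, textured vessel
#' wall (a radial base gradient plus spatially correlated noise whose
#' amplitude is the group's texture heterogeneity), reference muscle and
#' grey-matter regions, optional hyperintense IPH blob on pre-contrast T1.
#' Exported mainly for inspection; [generate_cohort()] drives it.
#'
#' @param geometry List with `centre`, `outer_axes`, `lumen_axes`,
#'   `lumen_centre`, `theta` (pixel units).
#' @param masks Mask list as produced by the generator (needs `outer_wall`,
#'   `lumen`, `plaque_roi`, `muscle_ref`, `grey_matter_ref`).
#' @param heterogeneity Noise scale (>= 0); 0 gives a noise-free annulus.
#' @param contrast One of "T1", "T2", "CE_T1".
#' @param iph Logical: add an IPH blob (only honoured on T1).
#' @param grid_size,pixel_spacing,slice_thickness Grid geometry.
#' @return A [roi_image]. The IPH blob pixels are recorded in
#'   `attr(, "iph_pixels")`.
#' @keywords internal
#' @export
render_plaque_image <- function(geometry, masks, heterogeneity, contrast = "T1",
                                iph = FALSE, grid_size = 64L,
                                pixel_spacing = 0.3, slice_thickness = 2) {
  n <- grid_size
  if (any(geometry$centre < 1) || any(geometry$centre > n) ||
      max(geometry$outer_axes) >= n / 2) {
    stop("vessel geometry lies outside the image grid", call. = FALSE)
  }
  base <- matrix(30, n, n)                                  # background
  wall_region <- ellipse_mask(n, geometry$centre,
                              geometry$outer_axes + 2, geometry$theta)
  base[wall_region] <- 95                                   # wall/plaque base
  base[masks$lumen] <- 40                                   # blood-suppressed lumen
  base[masks$muscle_ref] <- 100
  base[masks$grey_matter_ref] <- if (contrast == "CE_T1") 110 else 100
  img <- base
  # texture heterogeneity: spatially correlated noise over the wall whose
  # correlation length *shrinks* as heterogeneity grows (the kernel width is
  # the texture knob; the amplitude is normalised away by discretisation).
  # heterogeneity 0 leaves a constant-intensity annulus.
  if (heterogeneity > 0) {
    tex <- 10 * smooth_noise(n, sigma = 1 / heterogeneity)
    img[wall_region] <- img[wall_region] + tex[wall_region]
  }
  # receiver noise outside the wall only (reference ROI realism; the plaque
  # ROI texture is governed solely by the heterogeneity field)
  bgn <- 2 * matrix(stats::rnorm(n * n), n, n)
  img[!wall_region] <- img[!wall_region] + bgn[!wall_region]
  iph_px <- integer(0)
  if (iph && contrast == "T1") {
    plaque_idx <- which(masks$plaque_roi)
    seed_px <- sample(plaque_idx, 1L)
    k <- sample(3:8, 1L)
    # breadth-first growth over 8-connected plaque pixels: the blob is one
    # connected component by construction
    in_plaque <- masks$plaque_roi
    frontier <- seed_px; blob <- seed_px
    while (length(blob) < k && length(frontier) > 0) {
      r <- ((frontier - 1L) %% n) + 1L; c <- ((frontier - 1L) %/% n) + 1L
      nb <- cbind(rep(r, 8) + rep(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L), each = length(r)),
                  rep(c, 8) + rep(c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L), each = length(c)))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= n & nb[, 2] >= 1 & nb[, 2] <= n, , drop = FALSE]
      cand <- unique(nb[, 1] + (nb[, 2] - 1L) * n)
      cand <- setdiff(cand[in_plaque[cand]], blob)
      frontier <- cand
      blob <- c(blob, cand)
    }
    iph_px <- blob[seq_len(min(k, length(blob)))]
    img[iph_px] <- pmax(100 * stats::runif(length(iph_px), 1.6, 2.2), 156)
  }
  out <- roi_image(img, pixel_spacing, slice_thickness)
  attr(out, "iph_pixels") <- iph_px
  out
}

# One patient: draw latent parameters, build geometry + masks, render the
# three contrasts, rescale CE-T1 so the enhancement-ratio formula recovers
# the drawn value.
make_study <- function(id, group, spec) {
  g <- if (group == "acute_subacute_symptomatic") 1L else 2L
  px_area <- spec$pixel_spacing^2
  n <- spec$grid_size
  mla <- rtrunc_norm_meanadj(1, spec$mla_mean_sd[[g]][1],
                             spec$mla_mean_sd[[g]][2], lower = 0.6, upper = 14)
  parea <- rtrunc_norm_meanadj(1, spec$plaque_area_mean_sd[[g]][1],
                               spec$plaque_area_mean_sd[[g]][2],
                               lower = 4, upper = 31)
  er <- rtrunc_norm(1, spec$enhancement_mean_sd[[g]][1],
                    spec$enhancement_mean_sd[[g]][2], lower = -60)
  sten <- rtrunc_norm(1, spec$stenosis_mean_sd[[g]][1],
                      spec$stenosis_mean_sd[[g]][2], lower = 10, upper = 90)
  het <- spec$texture_heterogeneity[g] * exp(stats::rnorm(1, 0, 0.45))
  t2_het <- spec$t2_texture_heterogeneity * exp(stats::rnorm(1, 0, 0.6))
  iph <- stats::runif(1) < spec$iph_prevalence[g]

  outer_area <- min(mla + parea, 36)           # mm^2, capped to fit the grid
  centre <- n / 2 + stats::runif(2, -2, 2)
  theta <- stats::runif(1, 0, pi)
  ax_ratio <- stats::runif(1, 1, 1.5)
  # semi-axes in px from target areas: pi*a*b = area/px_area
  ab_out <- outer_area / px_area / pi
  a_out <- sqrt(ab_out * ax_ratio); b_out <- sqrt(ab_out / ax_ratio)
  ab_lum <- mla / px_area / pi
  lum_ratio <- stats::runif(1, 1, 1.3)
  a_lum <- sqrt(ab_lum * lum_ratio); b_lum <- sqrt(ab_lum / lum_ratio)
  # offset the lumen inside the outer ellipse (eccentric plaque), bounded so
  # the lumen stays strictly interior
  max_off <- 0.6 * (min(a_out, b_out) - max(a_lum, b_lum))
  off <- if (max_off > 0) stats::runif(2, -max_off / 2, max_off / 2) else c(0, 0)

  outer_wall <- ellipse_mask(n, centre, c(a_out, b_out), theta)
  lumen <- ellipse_mask(n, centre + off, c(a_lum, b_lum), theta)
  lumen <- lumen & outer_wall
  plaque <- outer_wall & !lumen
  muscle <- disc_mask(n, c(9, 9), 5)
  gm_radius <- sqrt(15 / pi) / spec$pixel_spacing      # ~15 mm^2 region
  grey <- disc_mask(n, c(n - 9, n - 9), gm_radius)
  masks <- list(lumen = lumen, outer_wall = outer_wall, plaque_roi = plaque,
                muscle_ref = muscle, grey_matter_ref = grey)
  geometry <- list(centre = centre, outer_axes = c(a_out, b_out),
                   lumen_axes = c(a_lum, b_lum), lumen_centre = centre + off,
                   theta = theta)

  t1 <- render_plaque_image(geometry, masks, het, "T1", iph = iph,
                            grid_size = n, pixel_spacing = spec$pixel_spacing,
                            slice_thickness = spec$slice_thickness)
  t2 <- render_plaque_image(geometry, masks, t2_het,
                            "T2", grid_size = n,
                            pixel_spacing = spec$pixel_spacing,
                            slice_thickness = spec$slice_thickness)
  ce <- render_plaque_image(geometry, masks, het, "CE_T1", grid_size = n,
                            pixel_spacing = spec$pixel_spacing,
                            slice_thickness = spec$slice_thickness)
  # rescale the CE-T1 plaque so the grey-matter-normalised enhancement
  # formula recovers the drawn value exactly
  gm_pre <- mean(t1$data[grey]); gm_post <- mean(ce$data[grey])
  pl_pre <- mean(t1$data[plaque])
  target_post <- pl_pre * (1 + er / 100) * gm_post / gm_pre
  ce$data[plaque] <- ce$data[plaque] * target_post / mean(ce$data[plaque])
  # MR intensities are arbitrary units that vary between scans (coil
  # positioning, gain): each sequence gets its own global scale factor.
  # Every downstream quantity of interest is normalised within-scan
  # (enhancement by grey matter, IPH by muscle, textures by discretisation),
  # so only non-normalised absolute-intensity statistics feel this.
  t1$data <- t1$data * exp(stats::rnorm(1, 0, 0.35))
  t2$data <- t2$data * exp(stats::rnorm(1, 0, 0.35))
  ce$data <- ce$data * exp(stats::rnorm(1, 0, 0.35))

  cp <- spec$covariate_probs
  # sex and smoking share variance with the imaging markers (risk factors
  # act through plaque biology, they are not independent signal on top of
  # it); the logit shift keeps the group marginals near the target rates
  mark <- 1.2 * (iph - spec$iph_prevalence[g]) +
    0.015 * (er - spec$enhancement_mean_sd[[g]][1])
  covariates <- list(
    age = stats::rnorm(1, spec$age_mean_sd[[g]][1], spec$age_mean_sd[[g]][2]),
    sex_male = stats::runif(1) < stats::plogis(stats::qlogis(cp$sex_male[g]) + mark),
    diabetes = stats::runif(1) < cp$diabetes[g],
    hypertension = stats::runif(1) < cp$hypertension[g],
    hyperlipidaemia = stats::runif(1) < cp$hyperlipidaemia[g],
    smoking = stats::runif(1) < stats::plogis(stats::qlogis(cp$smoking[g]) + mark))

  structure(list(
    patient_id = id, label = group, images = list(T1 = t1, T2 = t2, CE_T1 = ce),
    masks = masks, geometry = geometry, covariates = covariates,
    reference_lumen_area = mask_area(lumen, spec$pixel_spacing) /
      (1 - sten / 100)^2,
    drawn = list(mla = mla, plaque_area = parea, enhancement_ratio = er,
                 stenosis = sten, heterogeneity = het,
                 t2_heterogeneity = t2_het, iph = iph)),
    class = "plaque_study")
}

#' Generate a synthetic plaque cohort
#'
#' Draws `n_symptomatic + n_asymptomatic` studies with the group structure of
#' the spec; fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List of `plaque_study` objects (symptomatic first).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("need a cohort_spec", call. = FALSE)
  with_rng(spec$seed, {
    groups <- c(rep("acute_subacute_symptomatic", spec$n_symptomatic),
                rep("asymptomatic", spec$n_asymptomatic))
    ids <- sprintf("pat%03d", seq_along(groups))
    mapply(make_study, ids, groups, MoreArgs = list(spec = spec),
           SIMPLIFY = FALSE, USE.NAMES = FALSE)
  })
}

#' @export
print.plaque_study <- function(x, ...) {
  cat(sprintf("<plaque_study> %s [%s], plaque %d px, IPH drawn: %s\n",
              x$patient_id, x$label, sum(x$masks$plaque_roi),
              x$drawn$iph))
  invisible(x)
}

dilate1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-nr, ]
  out[-nr, ] <- out[-nr, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -nc]
  out[, -nc] <- out[, -nc] | mask[, -1]
  out
}

#' Perturb a study's segmentation to emulate a second reader
#'
#' Boundary pixels of the lumen and outer-wall masks are randomly flipped
#' (dilation/erosion candidates drawn independently), mimicking the
#' segmentation variability of an independent reviewer. The plaque ROI is
#' recomputed and the containment invariants re-established; reference ROIs
#' are untouched. `jitter_scale = 0` returns identical masks.
#'
#' @param study A `plaque_study`.
#' @param jitter_scale Expected boundary displacement in pixels (>= 0).
#' @param seed Integer seed.
#' @return A perturbed copy of `study`.
#' @export
perturb_segmentation <- function(study, jitter_scale = 1, seed = 1L) {
  stopifnot(jitter_scale >= 0)
  if (jitter_scale == 0) return(study)
  with_rng(seed, {
    jitter_mask <- function(mask) {
      steps <- ceiling(jitter_scale)
      p <- jitter_scale / steps
      for (s in seq_len(steps)) {
        grown <- dilate1(mask)
        shrunk <- mask & !dilate1(!mask)
        outer_b <- grown & !mask        # dilation candidates
        inner_b <- mask & !shrunk       # erosion candidates
        add <- outer_b & matrix(stats::runif(length(mask)) < p / 2, nrow(mask))
        rem <- inner_b & matrix(stats::runif(length(mask)) < p / 2, nrow(mask))
        mask <- (mask | add) & !rem
      }
      mask
    }
    lumen <- jitter_mask(study$masks$lumen)
    outer <- jitter_mask(study$masks$outer_wall)
    outer <- outer | dilate1(lumen)     # keep the lumen strictly interior
    plaque <- outer & !lumen
    if (!any(plaque) || !any(lumen)) {  # degenerate draw: fall back to original
      return(study)
    }
    out <- study
    out$masks$lumen <- lumen
    out$masks$outer_wall <- outer
    out$masks$plaque_roi <- plaque
    out
  })
}

#' Write a cohort to disk as NIfTI images plus a manifest CSV
#'
#' One NIfTI per contrast and per mask under `dir/<patient_id>/`, and a
#' manifest CSV (patient_id, label, covariates, file paths).
#'
#' @param cohort List of plaque studies.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(st) {
    pdir <- file.path(dir, st$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    paths <- character(0)
    for (sq in names(st$images)) {
      img <- st$images[[sq]]
      p <- file.path(pdir, paste0(sq, ".nii"))
      nii <- RNifti::asNifti(img$data)
      RNifti::pixdim(nii) <- img$pixel_spacing
      RNifti::writeNifti(nii, p)
      paths[paste0("path_", sq)] <- p
    }
    for (mk in names(st$masks)) {
      p <- file.path(pdir, paste0("mask_", mk, ".nii"))
      RNifti::writeNifti(RNifti::asNifti(st$masks[[mk]] * 1L), p)
      paths[paste0("path_mask_", mk)] <- p
    }
    cbind(data.frame(patient_id = st$patient_id, label = st$label,
                     reference_lumen_area = st$reference_lumen_area,
                     slice_thickness = st$images$T1$slice_thickness,
                     stringsAsFactors = FALSE),
          as.data.frame(st$covariates), as.data.frame(as.list(paths)))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest directory
#'
#' Inverse of [write_cohort()]: reconstructs the study list from the NIfTI
#' files and the manifest CSV.
#'
#' @param dir Directory containing `manifest.csv` and the per-patient files.
#' @return List of `plaque_study` objects (without the generator's latent
#'   `drawn` parameters).
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    read_img <- function(p) {
      nii <- RNifti::readNifti(p)
      roi_image(unclass(nii)[, , drop = TRUE],
                pixel_spacing = RNifti::pixdim(nii)[1:2],
                slice_thickness = row$slice_thickness)
    }
    images <- list(T1 = read_img(row$path_T1), T2 = read_img(row$path_T2),
                   CE_T1 = read_img(row$path_CE_T1))
    read_mask <- function(p) unclass(RNifti::readNifti(p))[, , drop = TRUE] == 1
    masks <- list(lumen = read_mask(row$path_mask_lumen),
                  outer_wall = read_mask(row$path_mask_outer_wall),
                  plaque_roi = read_mask(row$path_mask_plaque_roi),
                  muscle_ref = read_mask(row$path_mask_muscle_ref),
                  grey_matter_ref = read_mask(row$path_mask_grey_matter_ref))
    structure(list(
      patient_id = row$patient_id, label = row$label, images = images,
      masks = masks,
      covariates = list(age = row$age, sex_male = row$sex_male,
                        diabetes = row$diabetes,
                        hypertension = row$hypertension,
                        hyperlipidaemia = row$hyperlipidaemia,
                        smoking = row$smoking),
      reference_lumen_area = row$reference_lumen_area),
      class = "plaque_study")
  })
}
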