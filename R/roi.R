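#' 2D region-of-interest image
#'
#' Light container for a single analysed cross-sectional slice: an intensity
#' matrix plus the physical pixel geometry needed to report features in
#' millimetres.
#'
#' @param data Numeric matrix of signal intensities (rows x columns).
#' @param pixel_spacing Length-2 numeric, in-plane pixel size in mm
#'   (row direction, column direction). A scalar is recycled.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(data, pixel_spacing = 0.3, slice_thickness = 2) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix", call. = FALSE)
  }
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0) {
    stop("pixel spacing and slice thickness must be positive", call. = FALSE)
  }
  structure(
    list(data = data, pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness)),
    class = "roi_image"
  )
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %d x %d pixels, %.3g x %.3g mm, thickness %.3g mm\n",
              nrow(x$data), ncol(x$data), x$pixel_spacing[1],
              x$pixel_spacing[2], x$slice_thickness))
  invisible(x)
}

check_mask <- function(mask, data = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (!is.null(data) && !identical(dim(mask), dim(data))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  invisible(mask)
}

#' Discretise ROI intensities into equal-width grey-level bins
#'
#' Texture matrices are computed on grey-level labels, not raw intensities:
#' binning reduces noise and puts patients with different global signal
#' scaling on a common footing. Bins are equal width between the in-mask
#' minimum and maximum; the maximum intensity is assigned to the top bin.
#' A constant ROI maps every pixel to bin 1.
#'
#' @param roi A [roi_image] (or a bare numeric matrix).
#' @param mask Logical matrix selecting the ROI pixels.
#' @param n_bins Number of grey levels (>= 2).
#' @return An object of class `disc_roi` with fields `grid` (integer labels,
#'   `NA` outside the mask), `n_bins` and `bin_edges`.
#' @export
discretise <- function(roi, mask, n_bins = 32L) {
  data <- if (inherits(roi, "roi_image")) roi$data else roi
  check_mask(mask, data)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  vals <- data[mask]
  if (anyNA(vals)) stop("NA intensities inside the mask", call. = FALSE)
  lo <- min(vals); hi <- max(vals)
  grid <- matrix(NA_integer_, nrow(data), ncol(data))
  if (hi == lo) {
    grid[mask] <- 1L
    edges <- lo + seq(0, 1, length.out = n_bins + 1L)
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    lab <- floor((vals - lo) / (hi - lo) * n_bins) + 1L
    lab[lab > n_bins] <- n_bins
    grid[mask] <- as.integer(lab)
  }
  structure(list(grid = grid, n_bins = n_bins, bin_edges = edges),
            class = "disc_roi")
}
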