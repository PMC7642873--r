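#' Fixed-bin-width gray-level discretization of an ROI
#'
#' Assigns every in-ROI voxel a gray level via the min-anchored floor rule
#' `level(v) = floor((v - min_roi) / bin_width) + 1`, so texture features are
#' invariant to intensity shifts. A constant ROI maps to a single level.
#'
#' @param volume an [image_volume].
#' @param mask a [roi_mask] on the same grid.
#' @param bin_width intensity width of one gray-level bin (> 0). Default 25,
#'   intended for intensities normalized to SD 100 (see [normalize_volume]).
#' @return A `discretized_roi`: list with `levels` (integer 3D array, 0
#'   outside the ROI), `ng` (number of levels), `bin_width`, `spacing`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(volume, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    stop("bin_width must be a single positive number")
  inroi <- mask$voxels != 0L
  if (!any(inroi)) stop("mask is empty")
  vals <- volume$voxels[inroi]
  lev <- floor((vals - min(vals)) / bin_width) + 1
  levels <- array(0L, dim(volume$voxels))
  levels[inroi] <- as.integer(lev)
  structure(list(levels = levels, ng = as.integer(max(lev)),
                 bin_width = bin_width, spacing = volume$spacing),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi> %d gray levels, bin width %g, %d ROI voxels\n",
              x$ng, x$bin_width, sum(x$levels > 0L)))
  invisible(x)
}
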