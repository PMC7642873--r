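#' Occlusion sensitivity map for one radiomics feature
#'
#' Quantifies the regional contribution of image areas to a single radiomics
#' feature: a square in-plane mask (default 5x5 voxels, moving with stride 5)
#' is placed at each grid position on each axial slice intersecting the ROI
#' bounding box, the veiled patch is overwritten with a fill value ("black" =
#' the volume minimum by default), the feature is re-extracted over the
#' unchanged ROI, and the change versus the original value is recorded. A
#' higher map value means a greater contribution of the veiled portion.
#' Positions whose patch misses the ROI on that slice are recorded as 0; the
#' ROI mask itself is never altered.
#'
#' @param volume an [image_volume].
#' @param roi a nonempty [roi_mask] on the same grid.
#' @param feature_name namespaced feature, e.g. `"glcm_Correlation"`.
#' @param mask_size side length of the square occluder, voxels (default 5).
#' @param stride step between positions, voxels (default 5).
#' @param fill `"min"` (volume minimum, default) or a numeric fill value.
#' @param metric `"abs"` (|delta|, default), `"signed"` or `"relative"`
#'   (|delta| / (|original| + 1e-12)).
#' @param bin_width discretization width for texture features.
#' @return An `occlusion_map`: values array (x-positions, y-positions,
#'   slices) plus the position grid, slice indices and original feature value.
#' @export
occlusion_map <- function(volume, roi, feature_name, mask_size = 5, stride = 5,
                          fill = "min", metric = c("abs", "signed", "relative"),
                          bin_width = 25) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_mask"))
  metric <- match.arg(metric)
  if (mask_size < 1 || stride < 1) stop("mask_size and stride must be >= 1")
  if (n_foreground(roi) == 0) stop("empty ROI")
  f0 <- compute_single_feature(volume, roi, feature_name, bin_width)
  fill_value <- if (identical(fill, "min")) min(volume$voxels) else as.numeric(fill)

  idx <- which(roi$voxels != 0L, arr.ind = TRUE)
  bb <- apply(idx, 2, range)
  xs <- seq.int(bb[1, 1], bb[2, 1], by = stride)
  ys <- seq.int(bb[1, 2], bb[2, 2], by = stride)
  zs <- seq.int(bb[1, 3], bb[2, 3])
  d <- dim(volume$voxels)
  vals <- array(0, c(length(xs), length(ys), length(zs)))
  v <- volume$voxels
  work <- volume
  for (kz in seq_along(zs)) {
    z <- zs[kz]
    roi_slice <- roi$voxels[, , z]
    if (!any(roi_slice != 0L)) next
    for (kx in seq_along(xs)) {
      x0 <- xs[kx]; x1 <- min(x0 + mask_size - 1L, d[1])
      for (ky in seq_along(ys)) {
        y0 <- ys[ky]; y1 <- min(y0 + mask_size - 1L, d[2])
        if (!any(roi_slice[x0:x1, y0:y1] != 0L)) next
        patch <- v[x0:x1, y0:y1, z]
        v[x0:x1, y0:y1, z] <- fill_value
        work$voxels <- v
        fm <- compute_single_feature(work, roi, feature_name, bin_width)
        v[x0:x1, y0:y1, z] <- patch
        delta <- fm - f0
        vals[kx, ky, kz] <- switch(metric,
                                   abs = abs(delta),
                                   signed = delta,
                                   relative = abs(delta) / (abs(f0) + 1e-12))
      }
    }
  }
  structure(list(values = vals, feature_name = feature_name,
                 mask_size = mask_size, stride = stride,
                 fill_value = fill_value, metric = metric,
                 x_starts = xs, y_starts = ys, slices = zs,
                 original_value = f0, spacing = volume$spacing),
            class = "occlusion_map")
}

#' @export
print.occlusion_map <- function(x, ...) {
  cat(sprintf("<occlusion_map %s> %dx%d positions x %d slices, mask %d stride %d, max %.4g\n",
              x$feature_name, length(x$x_starts), length(x$y_starts),
              length(x$slices), x$mask_size, x$stride, max(x$values)))
  invisible(x)
}

#' Compare occlusion maps between a thin-slice and a down-sampled series
#'
#' Aligns the simulated-conventional map's slices back to the thin-series
#' slices they were copied from (SC slice k corresponds to thin slice
#' `(k-1) * keep_every + phase + 1`) and the shared in-plane position grid,
#' then summarizes the per-position differences.
#'
#' @param map_3d occlusion map computed on the thin series.
#' @param map_sc occlusion map computed on the down-sampled series.
#' @param keep_every,phase the down-sampler settings used for the SC series.
#' @return List with the aligned `difference` array (thin minus SC),
#'   `mean_abs_difference`, `rank_correlation` (Spearman over matched
#'   positions) and `n_matched`.
#' @export
compare_occlusion <- function(map_3d, map_sc, keep_every = 5, phase = 0) {
  stopifnot(inherits(map_3d, "occlusion_map"), inherits(map_sc, "occlusion_map"))
  if (!identical(map_3d$feature_name, map_sc$feature_name))
    stop("maps were computed for different features")
  src_z <- (map_sc$slices - 1L) * keep_every + phase + 1L
  kz3 <- match(src_z, map_3d$slices)
  ok <- !is.na(kz3)
  # the two ROI bounding boxes can be offset by a voxel or two, so match each
  # SC position to the nearest thin-series position within half a stride
  near <- function(sc, s3, stride) {
    i3 <- vapply(sc, function(p) {
      j <- which.min(abs(s3 - p))
      if (abs(s3[j] - p) <= stride / 2) j else NA_integer_
    }, integer(1))
    cbind(sc_idx = seq_along(sc), idx3 = i3)[!is.na(i3), , drop = FALSE]
  }
  mx <- near(map_sc$x_starts, map_3d$x_starts, map_3d$stride)
  my <- near(map_sc$y_starts, map_3d$y_starts, map_3d$stride)
  if (!any(ok) || nrow(mx) == 0 || nrow(my) == 0)
    stop("maps share no positions")
  a <- map_3d$values[mx[, "idx3"], my[, "idx3"], kz3[ok], drop = FALSE]
  b <- map_sc$values[mx[, "sc_idx"], my[, "sc_idx"], which(ok), drop = FALSE]
  dif <- a - b
  rc <- if (stats::sd(a) > 0 && stats::sd(b) > 0)
    stats::cor(as.vector(a), as.vector(b), method = "spearman") else NA_real_
  list(difference = dif,
       mean_abs_difference = mean(abs(dif)),
       rank_correlation = rc,
       n_matched = length(dif))
}
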