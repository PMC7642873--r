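#' Whole-volume intensity normalization
#'
#' Centers all gray values at the volume mean and scales by the volume
#' standard deviation (computed over every voxel, not only the ROI):
#' `x' = scale * (x - mean) / sd`. With the default `scale = 1` the output has
#' mean 0 and SD 1. Pipelines that discretize with a fixed bin width of 25
#' normalized-intensity units use `scale = 100`, so the bin width resolves
#' about a quarter of an intensity SD.
#'
#' @param volume an [image_volume] with non-constant intensities.
#' @param scale target standard deviation of the output (default 1).
#' @return A list with `volume` (the normalized [image_volume]) and `record`
#'   (mean and sd used, a `normalization_record`).
#' @export
normalize_volume <- function(volume, scale = 1) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$voxels
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))  # population SD over all voxels
  if (!is.finite(s) || s == 0)
    stop("cannot normalize a constant volume (sd = 0)")
  out <- volume
  out$voxels <- scale * (v - m) / s
  list(volume = out,
       record = structure(list(mean = m, sd = s, scale = scale),
                          class = "normalization_record"))
}

#' In-plane matrix interpolation
#'
#' Up-samples each axial slice to a target in-plane matrix size (e.g. 256x256
#' acquisition interpolated to 512x512 for clinical display) by bilinear
#' interpolation. In-plane spacing is scaled by the source/target ratio; the
#' through-plane axis is untouched.
#'
#' @param volume an [image_volume].
#' @param target length-2 target in-plane matrix size, at least the source
#'   size.
#' @return An [image_volume] on the finer in-plane grid.
#' @export
interpolate_inplane <- function(volume, target) {
  stopifnot(inherits(volume, "image_volume"))
  target <- as.integer(rep(target, length.out = 2))
  if (any(target <= 0)) stop("target matrix size must be positive")
  sd <- dim(volume$voxels)
  if (any(target < sd[1:2])) stop("target must be >= source in-plane size")
  if (all(target == sd[1:2])) return(volume)
  # pixel-center alignment: target index t maps to source (t+.5)*ns/nt - .5
  cx <- (seq_len(target[1]) - 0.5) * sd[1] / target[1] - 0.5
  cy <- (seq_len(target[2]) - 0.5) * sd[2] / target[2] - 0.5
  cz <- seq_len(sd[3]) - 1
  out <- interp_trilinear(volume$voxels, cx, cy, cz)
  image_volume(out,
               spacing = c(volume$spacing[1] * sd[1] / target[1],
                           volume$spacing[2] * sd[2] / target[2],
                           volume$spacing[3]),
               origin = volume$origin, modality = volume$modality)
}

# shared strided slice retention; returns index vector of retained slices
retained_slices <- function(n_slices, keep_every, phase) {
  if (keep_every < 1) stop("keep_every must be >= 1")
  if (phase < 0 || phase >= keep_every) stop("phase must be in [0, keep_every)")
  if (n_slices < keep_every) stop("fewer slices than keep_every")
  seq.int(phase + 1L, n_slices, by = keep_every)
}

#' Simulated-conventional down-sampling by slice retention
#'
#' Emulates a thick-interval acquisition from a thin-slice series by keeping
#' one of every `keep_every` slices (default 5: a 0.5 mm-interval series
#' becomes a 2.5 mm-interval series). Retained slices are bit-identical copies
#' of source slices -- no interpolation or averaging, which would introduce
#' blurring and partial-volume effects. The through-plane spacing is
#' multiplied by `keep_every` and the origin shifted by `phase` source
#' spacings; slice count is `ceiling((N - phase) / keep_every)`.
#'
#' @param volume an [image_volume] with at least `keep_every` slices.
#' @param keep_every retain one slice in every `keep_every` (default 5).
#' @param phase which interleave to keep, `0 <= phase < keep_every`.
#' @return The down-sampled [image_volume].
#' @export
downsample_to_sc <- function(volume, keep_every = 5, phase = 0) {
  stopifnot(inherits(volume, "image_volume"))
  keep <- retained_slices(dim(volume$voxels)[3], keep_every, phase)
  out <- volume$voxels[, , keep, drop = FALSE]
  image_volume(out,
               spacing = c(volume$spacing[1:2], volume$spacing[3] * keep_every),
               origin = volume$origin + c(0, 0, phase * volume$spacing[3]),
               modality = volume$modality)
}

#' Down-sample an ROI mask with the same slice-retention rule
#'
#' @param mask a [roi_mask].
#' @inheritParams downsample_to_sc
#' @return The [roi_mask] on the simulated-conventional grid; errors if no
#'   foreground voxel survives.
#' @export
downsample_mask <- function(mask, keep_every = 5, phase = 0) {
  stopifnot(inherits(mask, "roi_mask"))
  keep <- retained_slices(dim(mask$voxels)[3], keep_every, phase)
  out <- mask$voxels[, , keep, drop = FALSE]
  if (sum(out) == 0)
    stop("down-sampled mask is empty: no foreground on retained slices")
  roi_mask(out,
           spacing = c(mask$spacing[1:2], mask$spacing[3] * keep_every),
           origin = mask$origin + c(0, 0, phase * mask$spacing[3]))
}
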