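#' @useDynLib sliceomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' 3D image volume with voxel-spacing metadata
#'
#' The unit every pipeline stage consumes: a rank-3 scalar voxel array plus
#' anisotropic voxel spacing (mm per axis), a physical origin and a free-text
#' modality tag. Axis order is (x, y, z) with z the through-plane axis; voxel
#' indices are interpreted 0-based in all geometry computations.
#'
#' @param voxels numeric 3D array.
#' @param spacing numeric length-3, mm per axis (in-plane x, in-plane y,
#'   through-plane z); strictly positive.
#' @param origin numeric length-3, mm position of the first voxel center.
#' @param modality free-text tag (e.g. "CE-T1", "T2").
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = "") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a rank-3 array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 modality = as.character(modality)[1]),
            class = "image_volume")
}

#' Binary region-of-interest mask on a volume grid
#'
#' @param voxels logical or 0/1 numeric 3D array.
#' @inheritParams image_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("mask must be a rank-3 array")
  if (!all(voxels %in% c(0, 1, NA)))
    stop("mask voxels must be 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(list(voxels = array(as.integer(voxels != 0), dim(voxels)),
                 spacing = spacing, origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, origin %s mm\n",
              if (nzchar(x$modality)) x$modality else "untagged",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s grid, %d foreground voxels, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels), paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$voxels != 0L)

check_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("grids differ in shape")
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("grids differ in spacing")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [image_volume]; voxel spacing comes
#' from the header `pixdim`, the origin from the stored transform.
#'
#' @param path file path.
#' @param modality optional modality tag to attach.
#' @return An [image_volume].
#' @export
read_volume <- function(path, modality = "") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a rank-3 volume, got rank ", length(dim(img)))
  arr <- array(as.vector(img), dim(img))
  spacing <- attr(img, "pixdim")[1:3]
  origin <- as.numeric(RNifti::xform(img)[1:3, 4])
  image_volume(arr, spacing = spacing, origin = origin, modality = modality)
}

#' Write a NIfTI volume
#'
#' @param volume an [image_volume] or [roi_mask].
#' @param path destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "roi_mask"))
    volume <- image_volume(volume$voxels, volume$spacing, volume$origin, "mask")
  if (!inherits(volume, "image_volume")) stop("not an image_volume")
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  mat <- diag(4)
  diag(mat)[1:3] <- volume$spacing
  mat[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(mat, code = 2L)
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI ROI mask
#'
#' @inheritParams read_volume
#' @return A [roi_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (!all(v$voxels %in% c(0, 1)))
    stop("mask file contains values other than 0/1")
  roi_mask(v$voxels, v$spacing, v$origin)
}

#' Consensus ROI from two raters
#'
#' Implements the two-reader consensus rule: the disagreement between masks A
#' and B is measured as the Jaccard distance |A xor B| / |A union B|. If it is
#' at most `tolerance` the consensus is the overlap A intersect B; otherwise
#' the case is flagged for arbitration by a third reader.
#'
#' @param mask_a,mask_b [roi_mask] objects on the same grid.
#' @param tolerance maximum tolerated Jaccard distance (default 0.05).
#' @return A list with `mask` (the intersection [roi_mask], or `NULL`),
#'   `difference` (the Jaccard distance) and `needs_arbitration` (logical).
#' @export
consensus_roi <- function(mask_a, mask_b, tolerance = 0.05) {
  check_same_grid(mask_a, mask_b)
  a <- mask_a$voxels != 0L
  b <- mask_b$voxels != 0L
  uni <- sum(a | b)
  if (uni == 0) stop("both masks are empty")
  diff <- sum(xor(a, b)) / uni
  if (diff <= tolerance) {
    list(mask = roi_mask(a & b, mask_a$spacing, mask_a$origin),
         difference = diff, needs_arbitration = FALSE)
  } else {
    list(mask = NULL, difference = diff, needs_arbitration = TRUE)
  }
}

#' Resample a volume or mask to another grid
#'
#' Helper for grid mismatches: trilinear interpolation for images,
#' nearest-neighbour for masks, mapping physical (mm) coordinates between the
#' two grids.
#'
#' @param x an [image_volume] or [roi_mask].
#' @param shape target voxel counts per axis.
#' @param spacing target spacing (mm per axis).
#' @param origin target origin (mm).
#' @return Object of the same class on the target grid.
#' @export
resample_to_grid <- function(x, shape, spacing, origin = c(0, 0, 0)) {
  is_mask <- inherits(x, "roi_mask")
  src <- x$voxels
  sd <- dim(src)
  coords <- lapply(1:3, function(ax) {
    phys <- origin[ax] + (seq_len(shape[ax]) - 1) * spacing[ax]
    (phys - x$origin[ax]) / x$spacing[ax]  # 0-based source coordinate
  })
  if (is_mask) {
    ix <- lapply(1:3, function(ax) pmin(pmax(round(coords[[ax]]) + 1, 1), sd[ax]))
    out <- src[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    roi_mask(out, spacing, origin)
  } else {
    out <- interp_trilinear(src, coords[[1]], coords[[2]], coords[[3]])
    image_volume(out, spacing, origin, x$modality)
  }
}

# Trilinear interpolation of a 3D array at the tensor grid given by 0-based
# per-axis coordinates (clamped to the array support).
interp_trilinear <- function(src, cx, cy, cz) {
  sd <- dim(src)
  clamp <- function(v, n) pmin(pmax(v, 0), n - 1)
  cx <- clamp(cx, sd[1]); cy <- clamp(cy, sd[2]); cz <- clamp(cz, sd[3])
  x0 <- pmin(floor(cx), sd[1] - 1); x1 <- pmin(x0 + 1, sd[1] - 1)
  y0 <- pmin(floor(cy), sd[2] - 1); y1 <- pmin(y0 + 1, sd[2] - 1)
  z0 <- pmin(floor(cz), sd[3] - 1); z1 <- pmin(z0 + 1, sd[3] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  out <- array(0, c(nx, ny, nz))
  FX <- array(fx, c(nx, ny, nz))
  FY <- array(rep(fy, each = nx), c(nx, ny, nz))
  FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
  g <- function(ix, iy, iz)
    array(src[cbind(rep(ix + 1, times = ny * nz),
                    rep(rep(iy + 1, each = nx), times = nz),
                    rep(iz + 1, each = nx * ny))], c(nx, ny, nz))
  out <- g(x0, y0, z0) * (1 - FX) * (1 - FY) * (1 - FZ) +
         g(x1, y0, z0) * FX       * (1 - FY) * (1 - FZ) +
         g(x0, y1, z0) * (1 - FX) * FY       * (1 - FZ) +
         g(x1, y1, z0) * FX       * FY       * (1 - FZ) +
         g(x0, y0, z1) * (1 - FX) * (1 - FY) * FZ +
         g(x1, y0, z1) * FX       * (1 - FY) * FZ +
         g(x0, y1, z1) * (1 - FX) * FY       * FZ +
         g(x1, y1, z1) * FX       * FY       * FZ
  out
}
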