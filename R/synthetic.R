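#' Configuration for a synthetic LGG imaging cohort
#'
#' Defines the study conditions the generator emulates: a cohort of
#' lower-grade glioma cases with paired modalities (a thin-slice
#' contrast-enhanced T1-like series at 0.5 mm inter-slice spacing and a
#' thick-slice T2-like series), a contiguous ellipsoidal tumor ROI shared by
#' both grids, and class-dependent differences between 1p/19q co-deleted and
#' intact tumors in (a) the spatial correlation length of the within-ROI
#' texture and (b) ROI elongation. Defaults mirror the clinical cohort the
#' package models: 96 cases, 22 co-deleted (~22.9%), 78/96 training fraction,
#' ~65.6% IDH-mutant, ~46.9% grade III.
#'
#' @param n_cases number of cases.
#' @param codeletion_fraction fraction of 1p/19q co-deleted cases.
#' @param train_fraction fraction assigned to the training set by
#'   [split_cohort].
#' @param idh_mutation_fraction overall IDH-mutant fraction (every co-deleted
#'   case is IDH-mutant; the remainder is filled from intact cases).
#' @param grade3_fraction fraction of WHO grade III cases.
#' @param volume_shape voxel counts per axis of the thin-series grid.
#' @param thin_spacing mm per axis of the thin series (through-plane 0.5 mm).
#' @param thick_spacing mm per axis of the T2-like series (through-plane 6 mm).
#' @param texture_effect class-separation parameter (mm): co-deleted cases
#'   gain `0.5 * texture_effect` of Gaussian-kernel correlation length on the
#'   in-plane and on the through-plane texture components, which are jittered
#'   independently per case (so the through-plane component carries class
#'   information of its own). 0 makes the classes texture-exchangeable.
#' @param shape_effect class ROI-elongation delta: additional in-plane
#'   major/minor axis ratio in co-deleted cases. 0 removes the shape signal.
#' @param noise_sd SD of additive voxel noise inside the ROI, relative to the
#'   unit-variance texture field.
#' @param single_arm_fraction fraction of intact cases carrying a single-arm
#'   (1p or 19q) loss, still labelled intact.
#' @param seed integer RNG seed; the whole cohort is a deterministic function
#'   of the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 96,
                          codeletion_fraction = 22 / 96,
                          train_fraction = 78 / 96,
                          idh_mutation_fraction = 63 / 96,
                          grade3_fraction = 45 / 96,
                          volume_shape = c(40, 40, 32),
                          thin_spacing = c(0.5, 0.5, 0.5),
                          thick_spacing = c(0.5, 0.5, 6),
                          texture_effect = 0.4,
                          shape_effect = 0.15,
                          noise_sd = 0.8,
                          single_arm_fraction = 0.09,
                          seed = 1) {
  fr <- c(codeletion_fraction, train_fraction, idh_mutation_fraction,
          grade3_fraction, single_arm_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (n_cases < 1) stop("n_cases must be positive")
  if (any(volume_shape <= 0)) stop("volume_shape must be positive")
  if (thin_spacing[3] >= thick_spacing[3])
    stop("thin through-plane spacing must be smaller than thick")
  structure(list(n_cases = as.integer(n_cases),
                 codeletion_fraction = codeletion_fraction,
                 train_fraction = train_fraction,
                 idh_mutation_fraction = idh_mutation_fraction,
                 grade3_fraction = grade3_fraction,
                 volume_shape = as.integer(volume_shape),
                 thin_spacing = as.numeric(thin_spacing),
                 thick_spacing = as.numeric(thick_spacing),
                 texture_effect = texture_effect,
                 shape_effect = shape_effect,
                 noise_sd = noise_sd,
                 single_arm_fraction = single_arm_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' FISH arm-loss call from probe-count ratios
#'
#' A chromosome arm is called "loss" when its probe ratio (1p:1q, or 19q:19p)
#' is strictly below the threshold (default 0.75); the tumor is called
#' co-deleted only when both arms are lost.
#'
#' @param ratio_1p,ratio_19q nonnegative probe-count ratios.
#' @param threshold loss threshold (default 0.75, strict inequality).
#' @return List with `arm_1p`, `arm_19q` (`"loss"` / `"intact"`) and
#'   `combined` (`"codeleted"` / `"intact"`).
#' @export
fish_call <- function(ratio_1p, ratio_19q, threshold = 0.75) {
  if (ratio_1p < 0 || ratio_19q < 0) stop("ratios must be nonnegative")
  a1 <- if (ratio_1p < threshold) "loss" else "intact"
  a19 <- if (ratio_19q < threshold) "loss" else "intact"
  list(arm_1p = a1, arm_19q = a19,
       combined = if (a1 == "loss" && a19 == "loss") "codeleted" else "intact")
}

# separable Gaussian smoothing of a 3D array, sigma in voxels per axis;
# zero-padded edges (adequate for noise fields)
gauss_smooth3 <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 0.05) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[o + r + 1]
    }
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    dd <- dim(a)
    a <- array(K %*% matrix(a, dd[1]), dd)
    arr <- aperm(a, order(perm))
  }
  arr
}

# ellipsoid mask on a grid: semi-axes (a, b, c) mm, in-plane rotation theta
ellipsoid_mask <- function(shape, spacing, origin, center, axes, theta) {
  cx <- (seq_len(shape[1]) - 1) * spacing[1] + origin[1] - center[1]
  cy <- (seq_len(shape[2]) - 1) * spacing[2] + origin[2] - center[2]
  cz <- (seq_len(shape[3]) - 1) * spacing[3] + origin[3] - center[3]
  X <- array(cx, shape)
  Y <- array(rep(cy, each = shape[1]), shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), shape)
  U <- X * cos(theta) + Y * sin(theta)
  V <- -X * sin(theta) + Y * cos(theta)
  m <- (U / axes[1])^2 + (V / axes[2])^2 + (Z / axes[3])^2 <= 1
  array(as.integer(m), shape)
}

# one modality volume: smooth background + offset ROI carrying a
# unit-variance correlated texture field; sigma_mm is per axis (x, y, z)
synth_series <- function(shape, spacing, mask, sigma_mm, noise_sd, offset, tag) {
  bg <- gauss_smooth3(array(stats::rnorm(prod(shape)), shape), 3 / spacing)
  bg <- 0.2 * bg / max(stats::sd(bg), 1e-12) + 0.1 * stats::rnorm(prod(shape))
  tex <- gauss_smooth3(array(stats::rnorm(prod(shape)), shape), sigma_mm / spacing)
  inroi <- mask != 0L
  s <- stats::sd(tex[inroi])
  if (!is.finite(s) || s == 0) s <- 1
  tex <- tex / s
  vox <- array(bg, shape)
  vox[inroi] <- offset + tex[inroi] +
    noise_sd * stats::rnorm(sum(inroi))
  image_volume(vox, spacing, c(0, 0, 0), tag)
}

generate_case <- function(id, label, idh, grade, config) {
  shp <- config$volume_shape
  spt <- config$thin_spacing
  ext <- shp * spt
  # T2 grid shares the physical extent at thick through-plane spacing
  nz2 <- max(3L, as.integer(round(ext[3] / config$thick_spacing[3])))
  shp2 <- c(shp[1:2], nz2)
  sp2 <- config$thick_spacing

  center <- ext / 2 + stats::runif(3, -0.8, 0.8)
  # per-case biological variability: within-class spread of axis ratio and
  # correlation length is comparable to the class shift, so the classes
  # overlap as clinical cohorts do
  ratio <- stats::runif(1, 1.05, 1.35) +
    if (label == "codeleted") config$shape_effect else 0
  rc <- stats::runif(1, 0.8, 1.0)
  vol_target <- stats::runif(1, 550, 1100)          # mm^3, class-independent
  r <- (3 * vol_target / (4 * pi * ratio * rc))^(1 / 3)
  axes <- c(min(ratio * r, 8.5), r, rc * r)         # (major, minor, z) mm
  theta <- stats::runif(1, 0, pi)

  roi <- roi_mask(ellipsoid_mask(shp, spt, c(0, 0, 0), center, axes, theta),
                  spt, c(0, 0, 0))
  roi_t2 <- roi_mask(ellipsoid_mask(shp2, sp2, c(0, 0, 0), center, axes, theta),
                     sp2, c(0, 0, 0))

  # class-dependent correlation length with INDEPENDENT per-case jitter of
  # the in-plane and through-plane components: the through-plane component
  # then carries class information that in-plane texture cannot substitute,
  # and slice retention (2.5 mm interval > correlation length) destroys it.
  # Through-plane kernel widths are kept in the 0.35-0.6 mm range: large
  # enough that 0.5 mm-spaced neighbours see the class difference, small
  # enough that at a 2.5 mm interval the correlation is gone for BOTH
  # classes, so the retained-slice series cannot recover this component.
  eff <- if (label == "codeleted") config$texture_effect else 0
  base_xy <- 0.5 + stats::runif(1, -0.3, 0.3)
  base_z <- 0.35 + stats::runif(1, -0.15, 0.15)
  sigma <- pmax(0.15, c(base_xy + 0.5 * eff, base_xy + 0.5 * eff,
                        base_z + 0.5 * eff))
  thin <- synth_series(shp, spt, roi$voxels, sigma, config$noise_sd, 1.5, "CE-T1")
  t2 <- synth_series(shp2, sp2, roi_t2$voxels, sigma, config$noise_sd, 1.2, "T2")

  if (label == "codeleted") {
    fr <- stats::runif(2, 0.30, 0.70)
  } else if (stats::runif(1) < config$single_arm_fraction) {
    fr <- if (stats::runif(1) < 0.5) c(stats::runif(1, 0.30, 0.70), stats::runif(1, 0.80, 1.20))
          else c(stats::runif(1, 0.80, 1.20), stats::runif(1, 0.30, 0.70))
  } else {
    fr <- stats::runif(2, 0.80, 1.20)
  }

  structure(list(case_id = id, thin_series = thin, t2_series = t2,
                 roi = roi, roi_t2 = roi_t2,
                 label = label, idh = idh, grade = grade,
                 fish_ratios = c(ratio_1p = fr[1], ratio_19q = fr[2])),
            class = "synthetic_case")
}

#' Generate a synthetic imaging cohort
#'
#' Draws `n_cases` synthetic LGG cases under the configured study conditions.
#' Co-deleted cases carry a longer within-ROI spatial correlation length and a
#' larger in-plane axis ratio than intact cases (by `texture_effect` and
#' `shape_effect`); both modalities share the ROI geometry (generated
#' pre-aligned). Every co-deleted case is IDH-mutant, and the FISH ratios of
#' every case are consistent with its label under [fish_call].
#'
#' @param config a [cohort_config].
#' @return List of `synthetic_case` objects; deterministic given
#'   `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases
  set.seed(config$seed)

  n_codel <- round(n * config$codeletion_fraction)
  labels <- sample(c(rep("codeleted", n_codel), rep("intact", n - n_codel)))
  n_idh <- round(n * config$idh_mutation_fraction)
  idh <- ifelse(labels == "codeleted", "mutant", "wildtype")
  need <- max(0, n_idh - n_codel)
  intact_idx <- which(labels == "intact")
  if (need > 0 && length(intact_idx) > 0)
    idh[sample(intact_idx, min(need, length(intact_idx)))] <- "mutant"
  n_g3 <- round(n * config$grade3_fraction)
  grade <- rep("II", n)
  if (n_g3 > 0) grade[sample(n, n_g3)] <- "III"

  lapply(seq_len(n), function(i)
    generate_case(sprintf("case_%03d", i), labels[i], idh[i], grade[i], config))
}

#' Split a cohort into training and validation sets
#'
#' Unstratified random assignment: `round(n * train_fraction)` cases train,
#' the remainder validate (so class imbalance can differ between the two
#' sets, as in a real random split).
#'
#' @param cases list of cases (any list).
#' @param train_fraction fraction in (0, 1).
#' @param seed RNG seed controlling membership.
#' @return List with `train` and `validation` sublists (disjoint, exhaustive).
#' @export
split_cohort <- function(cases, train_fraction, seed) {
  if (length(cases) == 0) stop("empty cohort")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(cases)
  n_train <- round(n * train_fraction)
  set.seed(seed)
  idx <- sample(n, n_train)
  list(train = cases[sort(idx)], validation = cases[sort(setdiff(seq_len(n), idx))])
}
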