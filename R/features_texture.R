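# Texture feature families on a discretized ROI. Matrix construction lives in
# src/texture_kernels.cpp; this file holds the feature formulas. Conventions:
# distance-1 neighbourhoods on the voxel lattice (no mm correction -- this is
# exactly what makes thick-interval features diverge from thin-slice ones),
# GLCM/GLRLM computed per direction over the 13 unique 3D offsets with feature
# values averaged across directions, GLCM symmetrized and normalized per
# direction. Logs are base 2.

glcm_dims <- function(droi) {
  d <- dim(droi$levels)
  cpp_glcm_counts(as.integer(droi$levels), d[1], d[2], d[3], droi$ng)
}

#' Raw texture matrices of a discretized ROI
#'
#' Returns the unnormalized count matrices every texture family is computed
#' from: symmetrized GLCM pair counts and GLRLM run counts per direction
#' (level x level x 13 and level x run-length x 13 arrays, directions ordered
#' as the 13 unique 3D lattice offsets), the GLSZM zone-size counts, the GLDM
#' dependence counts (columns are dependence + 1) and the NGTDM per-level
#' `n_i` / `s_i` columns. Mainly useful for verification and inspection.
#'
#' @inheritParams glcm_features
#' @param alpha GLDM gray-level similarity tolerance.
#' @return List with elements `glcm`, `glrlm`, `glszm`, `gldm`, `ngtdm` and
#'   `directions` (the 13 x 3 offset matrix).
#' @export
texture_matrices <- function(droi, alpha = 0) {
  stopifnot(inherits(droi, "discretized_roi"))
  d <- dim(droi$levels)
  lv <- as.integer(droi$levels)
  list(glcm = cpp_glcm_counts(lv, d[1], d[2], d[3], droi$ng),
       glrlm = cpp_glrlm_counts(lv, d[1], d[2], d[3], droi$ng),
       glszm = cpp_glszm_counts(lv, d[1], d[2], d[3], droi$ng),
       gldm = cpp_gldm_counts(lv, d[1], d[2], d[3], droi$ng, as.integer(alpha)),
       ngtdm = cpp_ngtdm_stats(lv, d[1], d[2], d[3], droi$ng),
       directions = lattice_directions())
}

#' The 13 unique 3D lattice directions
#'
#' @return 13 x 3 integer matrix of the distance-1 neighbour offsets modulo
#'   sign, in the order used by the per-direction texture matrices.
#' @export
lattice_directions <- function() {
  matrix(c(1,0,0, 0,1,0, 0,0,1,
           1,1,0, 1,-1,0, 1,0,1, 1,0,-1, 0,1,1, 0,1,-1,
           1,1,1, 1,1,-1, 1,-1,1, 1,-1,-1),
         ncol = 3, byrow = TRUE)
}

#' Gray-level co-occurrence matrix features (24 features)
#'
#' Pair counts of adjacent gray levels at lattice distance 1, symmetrized and
#' normalized per direction; feature values are averaged over the 13 unique
#' 3D directions (directions with no in-ROI pairs are skipped). On a
#' single-level ROI the degenerate conventions Correlation = 1, IMC1 = 0,
#' IMC2 = 0, MCC = 1 apply and the result carries a `degenerate` attribute.
#'
#' @param droi a `discretized_roi` from [discretize].
#' @return Named numeric vector of length 24, names prefixed `glcm_`.
#' @export
glcm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  counts <- glcm_dims(droi)
  ng <- droi$ng
  acc <- NULL
  nd <- 0
  for (d in seq_len(13)) {
    P <- matrix(counts[, , d], ng, ng)
    tot <- sum(P)
    if (tot == 0) next
    f <- glcm_features_one(P / tot, ng)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) {  # ROI too small for any pair in any direction
    acc <- glcm_features_one(matrix(1, 1, 1), 1)
    nd <- 1
  }
  out <- acc / nd
  if (ng == 1) attr(out, "degenerate") <- TRUE
  out
}

glcm_features_one <- function(P, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)                       # symmetric: px == py
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)

  k_diff <- 0:(ng - 1)
  pdiff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  psum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))

  plog <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- plog(P)
  hx <- plog(px)
  pxpy <- outer(px, px)
  nz <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[nz] * log2(pxpy[nz]))
  hxy2 <- plog(pxpy)

  autoc <- sum(i * j * P)
  corr <- if (sig2 > 0) (autoc - mu^2) / sig2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  da <- sum(k_diff * pdiff)

  # MCC: sqrt of the second-largest eigenvalue of Q
  keep <- px > 0
  mcc <- 1
  if (sum(keep) > 1) {
    Ps <- P[keep, keep, drop = FALSE]
    pxs <- px[keep]
    # Q[i,j] = sum_k P[i,k] P[j,k] / (px[i] px[k])
    Q <- matrix(0, nrow(Ps), nrow(Ps))
    for (kk in seq_len(ncol(Ps)))
      Q <- Q + outer(Ps[, kk] / pxs, Ps[, kk]) / pxs[kk]
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(max(ev[2], 0), 1))
  }

  c(glcm_Autocorrelation = autoc,
    glcm_ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    glcm_ClusterShade = sum((i + j - 2 * mu)^3 * P),
    glcm_ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    glcm_Contrast = sum((i - j)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = plog(pdiff),
    glcm_DifferenceVariance = sum((k_diff - da)^2 * pdiff),
    glcm_Id = sum(pdiff / (1 + k_diff)),
    glcm_Idm = sum(pdiff / (1 + k_diff^2)),
    glcm_Idmn = sum(pdiff / (1 + (k_diff / ng)^2)),
    glcm_Idn = sum(pdiff / (1 + k_diff / ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = if (ng > 1) sum(pdiff[-1] / k_diff[-1]^2) else 0,
    glcm_JointAverage = mu,
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = hxy,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(k_sum * psum),
    glcm_SumEntropy = plog(psum),
    glcm_SumSquares = sig2)
}

# Shared size/length-distribution formulas for GLRLM (runs), GLSZM (zones)
# and GLDM (dependencies): P is a level x size count matrix, np the number of
# ROI voxels. `prefix` and `nm` give the family's feature names.
size_matrix_features <- function(P, np, names16) {
  ns <- sum(P)
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  s <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  p <- P / ns
  ri <- rowSums(P)     # per gray level
  rs <- colSums(P)     # per size
  mu_i <- sum(i * p)
  mu_s <- sum(s * p)
  plog <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  vals <- c(
    sum(P / s^2) / ns,          # small emphasis
    sum(P * s^2) / ns,          # large emphasis
    sum(ri^2) / ns,             # gray level non-uniformity
    sum(ri^2) / ns^2,           # ... normalized
    sum(rs^2) / ns,             # size non-uniformity
    sum(rs^2) / ns^2,           # ... normalized
    ns / np,                    # percentage
    sum(p * (i - mu_i)^2),      # gray level variance
    sum(p * (s - mu_s)^2),      # size variance
    plog(p),                    # entropy
    sum(P / i^2) / ns,          # low gray level emphasis
    sum(P * i^2) / ns,          # high gray level emphasis
    sum(P / (i^2 * s^2)) / ns,  # small + low
    sum(P * i^2 / s^2) / ns,    # small + high
    sum(P * s^2 / i^2) / ns,    # large + low
    sum(P * i^2 * s^2) / ns)    # large + high
  names(vals) <- names16
  vals
}

glrlm_names <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

#' Gray-level run-length matrix features (16 features)
#'
#' Counts of maximal constant-level voxel runs per (level, run length), one
#' matrix per direction over the 13 unique 3D directions; feature values are
#' averaged across directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16, names prefixed `glrlm_`.
#' @export
glrlm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  d <- dim(droi$levels)
  counts <- cpp_glrlm_counts(as.integer(droi$levels), d[1], d[2], d[3], droi$ng)
  np <- sum(droi$levels > 0L)
  acc <- NULL
  for (dd in seq_len(13)) {
    P <- matrix(counts[, , dd], droi$ng)
    f <- size_matrix_features(P, np, glrlm_names)
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / 13
  names(out) <- paste0("glrlm_", glrlm_names)
  out
}

glszm_names <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

#' Gray-level size-zone matrix features (16 features)
#'
#' Counts of 26-connected constant-level zones per (level, zone size); a
#' single matrix, no direction dependence.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16, names prefixed `glszm_`.
#' @export
glszm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  d <- dim(droi$levels)
  P <- cpp_glszm_counts(as.integer(droi$levels), d[1], d[2], d[3], droi$ng)
  np <- sum(droi$levels > 0L)
  out <- size_matrix_features(P, np, glszm_names)
  names(out) <- paste0("glszm_", glszm_names)
  out
}

gldm_names <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis", "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

#' Gray-level dependence matrix features (14 features)
#'
#' For every ROI voxel, its dependence is the number of 26-neighbours inside
#' the ROI whose level differs by at most `alpha` (default 0, i.e. equal
#' levels); the matrix counts (level, dependence + 1) pairs. Includes
#' Dependence Entropy.
#'
#' @inheritParams glcm_features
#' @param alpha gray-level similarity tolerance (default 0).
#' @return Named numeric vector of length 14, names prefixed `gldm_`.
#' @export
gldm_features <- function(droi, alpha = 0) {
  stopifnot(inherits(droi, "discretized_roi"))
  d <- dim(droi$levels)
  P <- cpp_gldm_counts(as.integer(droi$levels), d[1], d[2], d[3], droi$ng,
                       as.integer(alpha))
  ns <- sum(P)
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  j <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  p <- P / ns
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  plog <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  out <- c(sum(P / j^2) / ns,
           sum(P * j^2) / ns,
           sum(rowSums(P)^2) / ns,
           sum(colSums(P)^2) / ns,
           sum(colSums(P)^2) / ns^2,
           sum(p * (i - mu_i)^2),
           sum(p * (j - mu_j)^2),
           plog(p),
           sum(P / i^2) / ns,
           sum(P * i^2) / ns,
           sum(P / (i^2 * j^2)) / ns,
           sum(P * i^2 / j^2) / ns,
           sum(P * j^2 / i^2) / ns,
           sum(P * i^2 * j^2) / ns)
  names(out) <- paste0("gldm_", gldm_names)
  out
}

#' Neighbouring gray-tone difference matrix features (5 features)
#'
#' Per gray level, the summed absolute difference between a voxel's level and
#' the mean level of its in-ROI 26-neighbourhood; yields coarseness, contrast,
#' busyness, complexity and strength.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 5, names prefixed `ngtdm_`.
#' @export
ngtdm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  d <- dim(droi$levels)
  st <- cpp_ngtdm_stats(as.integer(droi$levels), d[1], d[2], d[3], droi$ng)
  ni <- st[, 1]; si <- st[, 2]
  nvp <- sum(ni)
  pi_ <- ni / nvp
  lev <- seq_len(droi$ng)
  act <- pi_ > 0
  ngp <- sum(act)
  ia <- lev[act]; pa <- pi_[act]; sa <- si[act]

  coarse <- { den <- sum(pa * sa); if (den > 0) 1 / den else 1e6 }
  contrast <- if (ngp > 1) {
    sum(outer(pa, pa) * outer(ia, ia, `-`)^2) / (ngp * (ngp - 1)) * sum(si) / nvp
  } else 0
  # double sums below run over ordered pairs; i = j terms contribute 0
  busy <- { den <- sum(abs(outer(ia * pa, ia * pa, `-`)))
            if (den > 0) sum(pa * sa) / den else 0 }
  cmplx <- {
    M <- abs(outer(ia, ia, `-`)) * (outer(pa * sa, pa * sa, `+`)) / outer(pa, pa, `+`)
    sum(M) / nvp
  }
  strength <- { den <- sum(si)
    if (den > 0) sum(outer(pa, pa, `+`) * outer(ia, ia, `-`)^2) / den else 0 }

  c(ngtdm_Coarseness = coarse,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busy,
    ngtdm_Complexity = cmplx,
    ngtdm_Strength = strength)
}
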