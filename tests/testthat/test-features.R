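test_that("discretization follows the min-anchored floor rule", {
  v <- image_volume(array(c(0, 24.9, 25, 50, 0, 0, 0, 0), c(2, 2, 2)))
  m <- roi_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)))
  dr <- discretize(v, m, 25)
  expect_equal(sort(dr$levels[dr$levels > 0]), c(1, 1, 2, 3))
  expect_equal(dr$ng, 3L)
  # constant ROI -> single level
  drc <- discretize(image_volume(array(4, c(2, 2, 2))),
                    roi_mask(array(1L, c(2, 2, 2))), 25)
  expect_equal(drc$ng, 1L)
  expect_error(discretize(v, m, 0), "positive")
})

test_that("shape features match closed forms on canonical masks", {
  sf <- shape_features(ball_mask(25, 10))
  expect_equal(length(sf), 14L)
  expect_equal(unname(sf["shape_Sphericity"]), 1, tolerance = 0.05)
  expect_equal(unname(sf["shape_MeshVolume"]), 4 / 3 * pi * 1000, tolerance = 0.05)
  expect_equal(unname(sf["shape_Maximum3DDiameter"]), 20, tolerance = 0.08)

  # 1x1x9 rod: major axis length = 4*sqrt(population variance of 0..8)
  rod <- array(0L, c(3, 3, 11)); rod[2, 2, 2:10] <- 1L
  sr <- shape_features(roi_mask(rod, c(1, 1, 1)))
  expect_equal(unname(sr["shape_MajorAxisLength"]), 4 * sqrt(60 / 9))
  expect_equal(unname(sr["shape_VoxelVolume"]), 9)

  # single voxel, spacing (1,1,1): voxel volume 1 mm^3
  sv <- array(0L, c(3, 3, 3)); sv[2, 2, 2] <- 1L
  expect_equal(unname(shape_features(roi_mask(sv))["shape_VoxelVolume"]), 1)
  expect_error(shape_features(roi_mask(array(0L, c(2, 2, 2)))), "empty")
})

test_that("shape features respect anisotropic spacing", {
  # 5-slice slab on a 2.5 mm grid spans the same mm extent as the thin version
  arr <- array(0L, c(9, 9, 21)); arr[3:7, 3:7, 5:15] <- 1L
  thin <- shape_features(roi_mask(arr, c(1, 1, 0.5)))
  expect_equal(unname(thin["shape_VoxelVolume"]), 25 * 11 * 0.5)
  # z extent (10 slices * 0.5) contributes to the 3D diameter
  expect_gt(unname(thin["shape_Maximum3DDiameter"]),
            unname(thin["shape_Maximum2DDiameterSlice"]))
})

test_that("first-order features match hand-computed values", {
  v <- image_volume(array(c(1, 2, 3, 0, 0, 0, 0, 0), c(2, 2, 2)))
  m <- roi_mask(array(c(1, 1, 1, 0, 0, 0, 0, 0), c(2, 2, 2)))
  fo <- firstorder_features(v, m, 1)
  expect_equal(length(fo), 18L)
  expect_equal(unname(fo["firstorder_Mean"]), 2)
  expect_equal(unname(fo["firstorder_Range"]), 2)
  expect_equal(unname(fo["firstorder_Energy"]), 1 + 4 + 9)

  # constant ROI: entropy 0, variance 0, uniformity 1
  fc <- firstorder_features(image_volume(array(5, c(2, 2, 2))),
                            roi_mask(array(1L, c(2, 2, 2))), 25)
  expect_equal(unname(fc["firstorder_Entropy"]), 0)
  expect_equal(unname(fc["firstorder_Variance"]), 0)
  expect_equal(unname(fc["firstorder_Uniformity"]), 1)

  # {1,1,2,2} with two bins: uniformity 0.5, entropy 1 bit
  v2 <- image_volume(array(c(1, 1, 2, 2), c(4, 1, 1)))
  m2 <- roi_mask(array(1L, c(4, 1, 1)))
  f2 <- firstorder_features(v2, m2, 1)
  expect_equal(unname(f2["firstorder_Uniformity"]), 0.5)
  expect_equal(unname(f2["firstorder_Entropy"]), 1)
})

test_that("GLCM single-direction matrix reproduces the textbook slab", {
  # [[1,1],[2,2]] one slice: along x both pairs are equal-level
  v <- image_volume(array(c(1, 1, 2, 2), c(2, 2, 1)))
  m <- roi_mask(array(1L, c(2, 2, 1)))
  tm <- texture_matrices(discretize(v, m, 1))
  P <- tm$glcm[, , 1]  # direction (1,0,0)
  expect_equal(P / sum(P), matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # Correlation of that matrix: mu 1.5, sigma^2 0.25 -> (2.5 - 2.25)/0.25 = 1
  p <- P / sum(P)
  mu <- sum(row(p) * p)
  corr <- (sum(row(p) * col(p) * p) - mu^2) / sum((row(p) - mu)^2 * p)
  expect_equal(corr, 1)
})

test_that("degenerate single-level ROI uses the documented conventions", {
  g <- glcm_features(discretize(image_volume(array(2, c(3, 3, 3))),
                                roi_mask(array(1L, c(3, 3, 3))), 25))
  expect_equal(unname(g["glcm_Correlation"]), 1)
  expect_equal(unname(g["glcm_Imc1"]), 0)
  expect_equal(unname(g["glcm_Imc2"]), 0)
  expect_equal(unname(g["glcm_MCC"]), 1)
  expect_equal(unname(g["glcm_JointEntropy"]), 0)
  expect_true(isTRUE(attr(g, "degenerate")))
})

test_that("GLCM matrices are symmetric and normalize to 1", {
  for (seed in 1:5) {
    dr <- rand_droi(c(5, 5, 4), 4, seed)
    tm <- texture_matrices(dr)
    for (d in 1:13) {
      P <- tm$glcm[, , d]
      expect_equal(P, t(P))
      if (sum(P) > 0) expect_equal(sum(P / sum(P)), 1)
    }
  }
})

test_that("GLRLM runs match explicit enumeration on a 1D ROI", {
  # [1,1,1,2] along x: runs (1,3) and (2,1) in direction 1
  v <- image_volume(array(c(1, 1, 1, 2), c(4, 1, 1)))
  m <- roi_mask(array(1L, c(4, 1, 1)))
  tm <- texture_matrices(discretize(v, m, 1))
  R <- tm$glrlm[, , 1]
  expect_equal(R[1, 3], 1)
  expect_equal(R[2, 1], 1)
  expect_equal(sum(R), 2)
  # orthogonal in-plane direction: four runs of length 1
  R2 <- tm$glrlm[, , 2]
  expect_equal(sum(R2[, 1]), 4)
})

test_that("GLSZM on a checkerboard finds only singleton zones", {
  # 4x4 checkerboard of levels {1,2}: under 26-connectivity every diagonal
  # neighbour shares the level, so zones are NOT singletons; verify against
  # the brute-force zone labelling oracle instead of an assumed count
  lv <- array(0L, c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) lv[x, y, 1] <- 1L + (x + y) %% 2L
  dr <- structure(list(levels = lv, ng = 2L, bin_width = 1, spacing = c(1, 1, 1)),
                  class = "discretized_roi")
  tm <- texture_matrices(dr)
  expect_equal(unname(tm$glszm), unname(oracle_glszm(lv, 2)))
  # with 4-separated singleton voxels the zones really are singletons
  lv2 <- array(0L, c(5, 5, 1)); lv2[c(1, 5), 1, 1] <- 1L; lv2[3, 3, 1] <- 2L
  dr2 <- structure(list(levels = lv2, ng = 2L, bin_width = 1, spacing = c(1, 1, 1)),
                   class = "discretized_roi")
  tm2 <- texture_matrices(dr2)
  expect_equal(tm2$glszm[1, 1], 2)
  expect_equal(tm2$glszm[2, 1], 1)
})

test_that("GLDM dependence of the center of a constant cube is 26", {
  dr <- discretize(image_volume(array(1, c(3, 3, 3))),
                   roi_mask(array(1L, c(3, 3, 3))), 25)
  tm <- texture_matrices(dr)
  expect_equal(tm$gldm[1, 27], 1)          # center voxel: 26 neighbours
  expect_equal(sum(tm$gldm), 27)           # every voxel contributes once
  g <- gldm_features(dr)
  p <- tm$gldm / sum(tm$gldm)
  p <- p[p > 0]
  expect_equal(unname(g["gldm_DependenceEntropy"]), -sum(p * log2(p)))
})

test_that("all five texture matrix families equal brute-force enumeration", {
  for (seed in 1:8) {
    dims <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    set.seed(seed * 17)
    dr <- rand_droi(dims, sample(2:5, 1), seed * 31)
    tm <- texture_matrices(dr)
    lv <- dr$levels; ng <- dr$ng
    expect_equal(unname(tm$glcm), unname(oracle_glcm(lv, ng)))
    expect_equal(unname(tm$glrlm[, seq_len(max(dims)), , drop = FALSE]),
                 unname(oracle_glrlm(lv, ng)[, seq_len(max(dims)), , drop = FALSE]))
    oz <- oracle_glszm(lv, ng)
    expect_equal(unname(tm$glszm[, seq_len(ncol(oz)), drop = FALSE]), unname(oz))
    if (ncol(tm$glszm) > ncol(oz)) expect_true(all(tm$glszm[, -seq_len(ncol(oz))] == 0))
    expect_equal(unname(tm$gldm), unname(oracle_gldm(lv, ng)))
    expect_equal(unname(tm$ngtdm), unname(oracle_ngtdm(lv, ng)))
  }
})

test_that("extraction yields exactly 107 features with the published partition", {
  v <- rand_volume(c(10, 10, 8), 21)
  m <- ball_mask(9, 3.4)
  m <- roi_mask(array(0L, c(10, 10, 8)))
  m$voxels[3:8, 3:8, 2:6] <- 1L
  fv <- extract_all(v, m, 0.25)
  expect_length(fv, 107L)
  fams <- table(sub("_.*", "", names(fv)))
  expect_equal(as.integer(fams[c("shape", "firstorder", "glcm", "glrlm",
                                 "glszm", "gldm", "ngtdm")]),
               c(14L, 18L, 24L, 16L, 16L, 14L, 5L))
  expect_false(anyNA(fv))
  # the clinically selected feature names exist
  expect_true(all(c("glcm_Imc2", "glcm_Correlation", "gldm_DependenceEntropy",
                    "shape_MajorAxisLength") %in% names(fv)))
  # determinism
  expect_identical(fv, extract_all(v, m, 0.25))
})

test_that("features are invariant to ROI translation and intensity shift", {
  set.seed(5)
  base <- array(rnorm(10 * 10 * 8), c(10, 10, 8))
  m1 <- array(0L, c(10, 10, 8)); m1[2:5, 2:5, 2:5] <- 1L
  m2 <- array(0L, c(10, 10, 8)); m2[5:8, 4:7, 3:6] <- 1L
  v1 <- image_volume(base)
  # translated copy: move the ROI content
  arr2 <- array(0, c(10, 10, 8))
  arr2[5:8, 4:7, 3:6] <- base[2:5, 2:5, 2:5]
  v2 <- image_volume(arr2)
  f1 <- extract_all(v1, roi_mask(m1), 0.25)
  f2 <- extract_all(v2, roi_mask(m2), 0.25)
  expect_equal(f1, f2, tolerance = 1e-12)
  # intensity shift: texture and histogram-shape features unchanged
  v3 <- image_volume(base + 7)
  f3 <- extract_all(v3, roi_mask(m1), 0.25)
  texture <- grep("^(glcm|glrlm|glszm|gldm|ngtdm)_", names(f1), value = TRUE)
  expect_equal(f1[texture], f3[texture], tolerance = 1e-10)
  expect_equal(unname(f3["firstorder_Mean"] - f1["firstorder_Mean"]), 7,
               tolerance = 1e-10)
})

test_that("direction-averaged texture features are invariant to 90-degree in-plane rotation", {
  set.seed(9)
  base <- array(rnorm(9 * 9 * 5), c(9, 9, 5))
  mk <- array(0L, c(9, 9, 5)); mk[3:7, 2:8, 2:4] <- 1L
  rot <- function(a) {
    out <- array(0, dim(a)[c(2, 1, 3)])
    for (z in seq_len(dim(a)[3])) out[, , z] <- t(a[, , z])[dim(a)[2]:1, ]
    out
  }
  f1 <- extract_all(image_volume(base), roi_mask(mk), 0.25)
  f2 <- extract_all(image_volume(rot(base)), roi_mask(array(as.integer(rot(mk) != 0), dim(rot(mk)))), 0.25)
  dirfeats <- grep("^(glcm|glrlm)_", names(f1), value = TRUE)
  expect_equal(f1[dirfeats], f2[dirfeats], tolerance = 1e-10)
})
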