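flat_fixture <- function() {
  arr <- array(1, c(20, 20, 3))
  v <- image_volume(arr)
  m <- array(0L, c(20, 20, 3)); m[4:17, 4:17, 1:3] <- 1L
  list(volume = v, mask = roi_mask(m))
}

test_that("masking with the veiled value itself yields an all-zero map", {
  fx <- flat_fixture()
  om <- occlusion_map(fx$volume, fx$mask, "firstorder_Mean",
                      mask_size = 5, stride = 5, fill = 1)
  expect_true(all(om$values == 0))
})

test_that("position grid follows the ceil(bbox extent / stride) rule", {
  arr <- array(0L, c(60, 60, 2)); arr[6:55, 6:55, 1:2] <- 1L  # 50x50 bbox
  m <- roi_mask(arr)
  v <- image_volume(array(rnorm(60 * 60 * 2), c(60, 60, 2)))
  om <- occlusion_map(v, m, "firstorder_Mean", mask_size = 5, stride = 5)
  expect_equal(length(om$x_starts) * length(om$y_starts), 100L)
  expect_equal(dim(om$values)[1:2], c(10L, 10L))
  # uneven extent: 23 voxels / stride 5 -> 5 positions
  arr2 <- array(0L, c(30, 30, 1)); arr2[2:24, 2:14, 1] <- 1L
  om2 <- occlusion_map(image_volume(array(1, c(30, 30, 1))), roi_mask(arr2),
                       "firstorder_Mean", 5, 5, fill = 1)
  expect_equal(length(om2$x_starts), ceiling(23 / 5))
  expect_equal(length(om2$y_starts), ceiling(13 / 5))
})

test_that("a planted bright patch is localized by the first-order maximum map", {
  fx <- flat_fixture()
  arr <- fx$volume$voxels
  # bright 5x5 patch aligned to the stride grid (ROI bbox starts at 4), so
  # exactly one occluder position veils it completely
  arr[9:13, 14:18, 2] <- 9
  v <- image_volume(arr)
  om <- occlusion_map(v, fx$mask, "firstorder_Maximum", 5, 5, fill = "min")
  pk <- which(om$values == max(om$values), arr.ind = TRUE)
  expect_gt(max(om$values), 0)
  expect_equal(om$x_starts[pk[1, 1]], 9)
  expect_equal(om$y_starts[pk[1, 2]], 14)
  expect_equal(om$slices[pk[1, 3]], 2L)
})

test_that("pure shape features give an all-zero occlusion map", {
  fx <- flat_fixture()
  v <- image_volume(array(rnorm(20 * 20 * 3), c(20, 20, 3)))
  om <- occlusion_map(v, fx$mask, "shape_MajorAxisLength", 5, 5)
  expect_true(all(om$values == 0))
})

test_that("occlusion comparison of an identical pair is exact", {
  set.seed(33)
  v <- image_volume(array(rnorm(20 * 20 * 5), c(20, 20, 5)), c(1, 1, 0.5))
  m <- array(0L, c(20, 20, 5)); m[5:16, 5:16, 1:5] <- 1L
  mk <- roi_mask(m, c(1, 1, 0.5))
  om1 <- occlusion_map(v, mk, "firstorder_Mean", 4, 4)
  # keep_every = 1 is the identity down-sampling
  v2 <- downsample_to_sc(v, 1)
  om2 <- occlusion_map(v2, downsample_mask(mk, 1), "firstorder_Mean", 4, 4)
  cmp <- compare_occlusion(om1, om2, keep_every = 1, phase = 0)
  expect_equal(cmp$mean_abs_difference, 0)
  expect_true(all(cmp$difference == 0))
  expect_equal(cmp$rank_correlation, 1)
  expect_error(compare_occlusion(om1, occlusion_map(v, mk, "firstorder_Maximum", 4, 4)),
               "different features")
})

test_that("re-sampling perturbs adjacency-based occlusion maps more than first-order maps", {
  # through-plane correlation length below the SC slice interval: the GLCM
  # feature's regional contributions should be reorganized by slice retention
  # while the first-order mean's are nearly preserved
  res <- vapply(1:10, function(s) {
    cs <- generate_cohort(cohort_config(n_cases = 1, volume_shape = c(28, 28, 22),
                                        seed = 3000 + s))[[1]]
    nrm <- function(v) normalize_volume(v, 100)$volume
    thin <- nrm(cs$thin_series)
    scv <- nrm(downsample_to_sc(cs$thin_series, 5, 0))
    scm <- downsample_mask(cs$roi, 5, 0)
    one <- function(fn) {
      cm <- compare_occlusion(
        occlusion_map(thin, cs$roi, fn, 5, 5, metric = "relative"),
        occlusion_map(scv, scm, fn, 5, 5, metric = "relative"), 5, 0)
      c(cm$rank_correlation, cm$mean_abs_difference)
    }
    c(one("glcm_Correlation"), one("firstorder_Mean"))
  }, numeric(4))
  glcm_rc <- res[1, ]; glcm_mad <- res[2, ]
  fo_rc <- res[3, ]; fo_mad <- res[4, ]
  expect_lt(mean(glcm_rc), mean(fo_rc))
  expect_gt(mean(glcm_mad), mean(fo_mad))
  expect_gte(mean(glcm_rc < fo_rc), 0.8)
})

test_that("texture occlusion maps respond to structure, unknown features error", {
  set.seed(44)
  v <- image_volume(array(rnorm(16 * 16 * 3), c(16, 16, 3)))
  m <- array(0L, c(16, 16, 3)); m[3:14, 3:14, 1:3] <- 1L
  mk <- roi_mask(m)
  om <- occlusion_map(v, mk, "glcm_Correlation", 5, 5, bin_width = 0.25)
  expect_gt(max(om$values), 0)
  expect_true(all(om$values >= 0))
  expect_error(occlusion_map(v, mk, "glcm_NoSuchThing"), "unknown feature")
  expect_error(occlusion_map(v, mk, "firstorder_Mean", 0, 5), ">= 1")
})
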