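#' First-order intensity features (18 features)
#'
#' Voxel-histogram statistics of the in-ROI intensities. Entropy and
#' uniformity are computed on the fixed-bin-width discretized histogram (same
#' rule as [discretize]); entropy is in bits. Variance, skewness and kurtosis
#' use population (1/N) moments; kurtosis is non-excess (3 for a Gaussian).
#'
#' @param volume an [image_volume].
#' @param mask a nonempty [roi_mask] on the same grid.
#' @param bin_width histogram bin width for entropy/uniformity (default 25).
#' @return Named numeric vector of length 18, names prefixed `firstorder_`.
#' @export
firstorder_features <- function(volume, mask, bin_width = 25) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  check_same_grid(volume, mask)
  x <- volume$voxels[mask$voxels != 0L]
  if (length(x) == 0) stop("mask is empty")
  n <- length(x)
  mu <- mean(x)
  p10 <- unname(stats::quantile(x, 0.10, type = 7))
  p90 <- unname(stats::quantile(x, 0.90, type = 7))
  va <- mean((x - mu)^2)
  sdev <- sqrt(va)
  xr <- x[x >= p10 & x <= p90]
  lev <- floor((x - min(x)) / bin_width)
  p <- tabulate(lev + 1) / n
  p <- p[p > 0]
  skew <- if (sdev > 0) mean((x - mu)^3) / sdev^3 else 0
  kurt <- if (sdev > 0) mean((x - mu)^4) / va^2 else 0

  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = prod(volume$spacing) * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = p10,
    firstorder_90Percentile = p90,
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = stats::median(x),
    firstorder_InterquartileRange =
      unname(stats::quantile(x, 0.75, type = 7) - stats::quantile(x, 0.25, type = 7)),
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Variance = va,
    firstorder_Uniformity = sum(p^2))
}
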