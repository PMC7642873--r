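#' Extract the full 107-feature radiomics vector
#'
#' Computes all 107 features over the ROI of one imaging volume: 14 shape,
#' 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features,
#' in that order, with names namespaced `family_FeatureName`.
#'
#' @param volume an [image_volume].
#' @param mask a nonempty [roi_mask] on the same grid.
#' @param bin_width gray-level bin width for discretization (default 25; see
#'   [discretize]).
#' @return Named numeric vector of length 107.
#' @export
extract_all <- function(volume, mask, bin_width = 25) {
  droi <- discretize(volume, mask, bin_width)
  out <- c(shape_features(mask),
           firstorder_features(volume, mask, bin_width),
           glcm_features(droi),
           glrlm_features(droi),
           glszm_features(droi),
           gldm_features(droi),
           ngtdm_features(droi))
  stopifnot(length(out) == 107L)
  attributes(out) <- list(names = names(out))
  out
}

#' Feature-family cardinalities
#'
#' @return Named integer vector giving the number of features per family.
#' @export
feature_counts <- function() {
  c(shape = 14L, firstorder = 18L, glcm = 24L, glrlm = 16L,
    glszm = 16L, gldm = 14L, ngtdm = 5L)
}

# Compute one named feature (e.g. "glcm_Correlation") by evaluating only its
# family; used by the occlusion mapper where the feature is re-extracted at
# every mask position.
compute_single_feature <- function(volume, mask, feature_name, bin_width = 25) {
  family <- sub("_.*$", "", feature_name)
  vals <- switch(family,
    shape = shape_features(mask),
    firstorder = firstorder_features(volume, mask, bin_width),
    glcm = glcm_features(discretize(volume, mask, bin_width)),
    glrlm = glrlm_features(discretize(volume, mask, bin_width)),
    glszm = glszm_features(discretize(volume, mask, bin_width)),
    gldm = gldm_features(discretize(volume, mask, bin_width)),
    ngtdm = ngtdm_features(discretize(volume, mask, bin_width)),
    stop("unknown feature family in '", feature_name, "'"))
  if (!feature_name %in% names(vals))
    stop("unknown feature name '", feature_name, "'")
  unname(vals[feature_name])
}
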