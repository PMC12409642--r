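# Radiomic feature-name taxonomy (PyRadiomics naming convention).

.fo_features <- c(
  "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
  "Kurtosis", "Maximum", "MeanAbsoluteDeviation", "Mean", "Median", "Minimum",
  "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
  "TotalEnergy", "Uniformity", "Variance"
)

.glcm_features <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)

.glrlm_features <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis"
)

.glszm_features <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance"
)

.ngtdm_features <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                     "Strength")

.gldm_features <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis"
)

.shape_features <- c(
  "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "Maximum2DDiameterSlice",
  "Maximum3DDiameter", "MeshVolume", "MinorAxisLength", "Sphericity",
  "SurfaceArea", "SurfaceVolumeRatio", "VoxelVolume"
)

.feature_classes <- function() {
  list(firstorder = .fo_features, glcm = .glcm_features,
       glrlm = .glrlm_features, glszm = .glszm_features,
       ngtdm = .ngtdm_features, gldm = .gldm_features)
}

.image_variants <- function() {
  c("original",
    paste0("wavelet-", c("LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH",
                         "LLL")),
    "log-sigma-1-mm-3D", "square", "squareroot", "exponential", "logarithm")
}

#' Generate the radiomic feature-name taxonomy
#'
#' Builds the ordered list of feature names produced by a whole-liver CT
#' radiomic extraction: 93 intensity/texture features (18 first-order,
#' 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM) computed on the original
#' image and 13 derived images (8 wavelet decompositions, Laplacian of
#' Gaussian at sigma = 1 mm, square, square root, exponential, logarithm),
#' plus 14 shape features computed on the original image only, for a total
#' of 93 x 14 + 14 = 1316 names. Names follow the PyRadiomics convention
#' \code{<image>_<class>_<feature>}, e.g. \code{wavelet-LHL_glcm_Contrast}.
#'
#' @param with_derived_images if \code{FALSE}, only original-image features
#'   are returned (93 intensity/texture + 14 shape = 107 names).
#' @return character vector of unique feature names.
#' @export
#' @examples
#' length(generate_feature_names())        # 1316
#' length(generate_feature_names(FALSE))   # 107
generate_feature_names <- function(with_derived_images = TRUE) {
  images <- if (with_derived_images) .image_variants() else "original"
  classes <- .feature_classes()
  nm <- unlist(lapply(images, function(img) {
    unlist(lapply(names(classes), function(cl) {
      paste(img, cl, classes[[cl]], sep = "_")
    }), use.names = FALSE)
  }), use.names = FALSE)
  c(nm, paste("original", "shape", .shape_features, sep = "_"))
}
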