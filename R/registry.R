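#' The default radiomic feature registry
#'
#' The default composition is 13 shape features (computed once, on the
#' original-resolution resampled mask) plus 52 per-channel features (16
#' first-order + 24 GLCM + 12 GLRLM) on each of 9 intensity channels (the
#' original image and the 8 stationary-wavelet sub-bands), totalling
#' 13 + 9 x 52 = 481 features. Feature names are
#' `<channel>_<family>_<statistic>`; the registry fixes the column order of
#' every feature table the package writes.
#'
#' @param wavelet include the 8 wavelet channels (default TRUE; with FALSE
#'   the registry shrinks to 13 + 52 = 65 features).
#' @return `data.frame` with columns `name`, `channel`, `family`,
#'   `formula_id`.
#' @examples
#' nrow(feature_registry())  # 481
#' @export
feature_registry <- function(wavelet = TRUE) {
  shape_names <- c("volume_mm3", "surface_area_mm2", "sphericity",
                   "compactness1", "compactness2", "spherical_disproportion",
                   "maximum_3d_diameter", "major_axis_length",
                   "minor_axis_length", "least_axis_length", "elongation",
                   "flatness", "surface_volume_ratio")
  fo_names <- c("minimum", "maximum", "mean", "median", "range", "variance",
                "standard_deviation", "skewness", "kurtosis", "energy",
                "entropy", "uniformity", "mean_absolute_deviation",
                "root_mean_square", "percentile_10", "percentile_90")
  channels <- "original"
  if (wavelet) {
    channels <- c(channels, paste0("wavelet.", c("LLL", "HLL", "LHL", "HHL",
                                                 "LLH", "HLH", "LHH", "HHH")))
  }
  rows <- data.frame(name = paste0("shape_", shape_names),
                     channel = "original", family = "shape",
                     formula_id = paste0("shape.", shape_names),
                     stringsAsFactors = FALSE)
  for (ch in channels) {
    rows <- rbind(rows,
      data.frame(name = paste0(ch, "_firstorder_", fo_names),
                 channel = ch, family = "first-order",
                 formula_id = paste0("fo.", fo_names),
                 stringsAsFactors = FALSE),
      data.frame(name = paste0(ch, "_glcm_", glcm_feature_names),
                 channel = ch, family = "GLCM",
                 formula_id = paste0("glcm.", glcm_feature_names),
                 stringsAsFactors = FALSE),
      data.frame(name = paste0(ch, "_glrlm_", glrlm_feature_names),
                 channel = ch, family = "GLRLM",
                 formula_id = paste0("glrlm.", glrlm_feature_names),
                 stringsAsFactors = FALSE))
  }
  stopifnot(!anyDuplicated(rows$name))
  rows
}
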