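#' Extraction configuration
#'
#' @param n_levels gray levels for texture discretization (default 32,
#'   equal-width bins over the VOI range, recomputed per channel).
#' @param distance GLCM offset distance in voxels (default 1).
#' @param resample_mm isotropic target spacing in mm before extraction
#'   (default 1; `NA` disables resampling).
#' @param wavelet extract the 8 wavelet channels (default TRUE).
#' @return a list of class `extraction_config`.
#' @export
extraction_config <- function(n_levels = 32L, distance = 1L,
                              resample_mm = 1, wavelet = TRUE) {
  stopifnot(n_levels >= 2L, distance >= 1L,
            is.na(resample_mm) || resample_mm > 0)
  structure(list(n_levels = as.integer(n_levels),
                 distance = as.integer(distance),
                 resample_mm = resample_mm, wavelet = isTRUE(wavelet)),
            class = "extraction_config")
}

#' Extract the full radiomic feature vector from one image/mask pair
#'
#' Runs the full extraction chain: isotropic resampling, shape features on
#' the mask, then per channel (original image plus the 8 stationary-wavelet
#' sub-bands) equal-width discretization, 16 first-order, 24
#' direction-averaged GLCM and 12 direction-averaged GLRLM features. With
#' the default registry this yields exactly 481 finite values in a fixed
#' order.
#'
#' @param img an [image_volume].
#' @param mask the paired [mask_volume].
#' @param config an [extraction_config].
#' @param patient_id optional id used in error messages.
#' @return named numeric vector in registry order, with the registry
#'   `data.frame` attached as attribute `"registry"`.
#' @export
extract_all <- function(img, mask, config = extraction_config(),
                        patient_id = "<unknown>") {
  validate_pair(img, mask)
  if (!is.na(config$resample_mm)) {
    rs <- resample_isotropic(img, mask, config$resample_mm)
    img <- rs$img; mask <- rs$mask
  }
  reg <- feature_registry(wavelet = config$wavelet)
  out <- numeric(0)
  fam_try <- function(channel, family, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("feature extraction failed for patient %s, channel %s, family %s: %s",
                   patient_id, channel, family, conditionMessage(e)),
           call. = FALSE)
    })
  }
  shp <- fam_try("original", "shape", shape_features(mask))
  out <- c(out, stats::setNames(shp, paste0("shape_", names(shp))))
  # texture is computed on the VOI bounding box for speed; features only
  # involve voxels inside the VOI, so cropping does not change them
  bbox <- mask_bbox(mask)
  mask_c <- crop_to_bbox(mask, bbox)
  channels <- list(original = crop_to_bbox(img, bbox))
  if (config$wavelet) {
    bands <- wavelet_channels(img)
    for (nm in names(bands)) {
      channels[[paste0("wavelet.", nm)]] <- crop_to_bbox(bands[[nm]], bbox)
    }
  }
  dirs <- glcm_directions()
  for (ch in names(channels)) {
    cimg <- channels[[ch]]
    fo <- fam_try(ch, "first-order",
                  first_order_features(cimg, mask_c, config$n_levels))
    dis <- discretize(cimg, mask_c, config$n_levels)
    glcms <- lapply(seq_len(nrow(dirs)), function(k)
      glcm_build(dis, dirs[k, ], delta = config$distance))
    gl <- fam_try(ch, "GLCM", glcm_features(glcms))
    glrlms <- lapply(seq_len(nrow(dirs)), function(k)
      glrlm_build(dis, dirs[k, ]))
    gr <- fam_try(ch, "GLRLM", glrlm_features(glrlms))
    out <- c(out,
             stats::setNames(fo, paste0(ch, "_firstorder_", names(fo))),
             stats::setNames(gl, paste0(ch, "_glcm_", names(gl))),
             stats::setNames(gr, paste0(ch, "_glrlm_", names(gr))))
  }
  out <- out[reg$name]
  if (any(!is.finite(out))) {
    bad <- reg$name[!is.finite(out)]
    stop(sprintf("non-finite feature value(s) for patient %s: %s", patient_id,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  attr(out, "registry") <- reg
  out
}

#' Extract features for a whole cohort
#'
#' @param volumes named list: for each patient id, a list with elements
#'   `img` ([image_volume]) and `mask` ([mask_volume]).
#' @param config an [extraction_config].
#' @param verbose print one log line per patient.
#' @return `data.frame` with `patient_id` plus one column per registry
#'   feature.
#' @export
extract_cohort <- function(volumes, config = extraction_config(),
                           verbose = FALSE) {
  stopifnot(length(volumes) >= 1L, !is.null(names(volumes)))
  reg <- feature_registry(wavelet = config$wavelet)
  mat <- matrix(NA_real_, nrow = length(volumes), ncol = nrow(reg),
                dimnames = list(NULL, reg$name))
  for (k in seq_along(volumes)) {
    id <- names(volumes)[k]
    v <- extract_all(volumes[[k]]$img, volumes[[k]]$mask, config,
                     patient_id = id)
    mat[k, ] <- as.numeric(v)
    if (verbose) {
      message(sprintf("extract patient=%s features=%d", id, ncol(mat)))
    }
  }
  cbind(data.frame(patient_id = names(volumes), stringsAsFactors = FALSE),
        as.data.frame(mat))
}
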