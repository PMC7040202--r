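#' Discretize VOI intensities into equal-width gray levels
#'
#' Intensities inside the VOI are binned into `n_levels` equal-width bins
#' spanning the VOI's [min, max]; the maximum intensity maps to level
#' `n_levels`. Voxels outside the VOI become `NA`. A constant VOI collapses
#' to level 1 and is flagged.
#'
#' @param img an [image_volume].
#' @param mask the paired [mask_volume].
#' @param n_levels number of gray levels (>= 2, default 32).
#' @return list with `levels` (integer 3D array, `NA` outside the VOI),
#'   `n_levels`, and `constant` flag.
#' @export
discretize <- function(img, mask, n_levels = 32L) {
  validate_pair(img, mask)
  stopifnot(n_levels >= 2L)
  v <- img$voxels
  inside <- mask$voxels > 0
  vals <- v[inside]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim = dim(v))
  if (hi - lo <= 0) {
    lev[inside] <- 1L
    return(list(levels = lev, n_levels = as.integer(n_levels), constant = TRUE))
  }
  width <- (hi - lo) / n_levels
  g <- pmin(floor((vals - lo) / width) + 1L, n_levels)
  lev[inside] <- as.integer(g)
  list(levels = lev, n_levels = as.integer(n_levels), constant = FALSE)
}
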