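#' 3D stationary wavelet decomposition into 8 sub-band channels
#'
#' Single-level undecimated (stationary) 3D wavelet transform with the coif1
#' filter bank and whole-sample reflection padding. Each axis is filtered
#' with either the low-pass (L) or high-pass (H) decomposition filter; the 8
#' combinations give the sub-bands LLL, HLL, LHL, HHL, LLH, HLH, LHH, HHH
#' (letter order = axis order x, y, z). Because the transform is
#' undecimated, every band keeps the original grid, so the original tumor
#' mask applies to every channel unchanged.
#'
#' @param img an [image_volume].
#' @return named list of 8 [image_volume]s (`LLL` ... `HHH`).
#' @examples
#' img <- image_volume(array(rnorm(512), c(8, 8, 8)))
#' bands <- wavelet_channels(img)
#' names(bands)
#' @export
wavelet_channels <- function(img) {
  stopifnot(inherits(img, "image_volume"))
  lo <- coif1_dec_lo
  hi <- coif1_dec_hi
  if (any(dim(img$voxels) < length(lo))) {
    warning("volume smaller than the wavelet filter support; reflection padding dominates")
  }
  x  <- img$voxels
  ax1 <- list(L = conv_axis(x, lo, 1L), H = conv_axis(x, hi, 1L))
  out <- list()
  for (a in c("L", "H")) {
    ax2 <- list(L = conv_axis(ax1[[a]], lo, 2L), H = conv_axis(ax1[[a]], hi, 2L))
    for (b in c("L", "H")) {
      for (cc in c("L", "H")) {
        k <- if (cc == "L") lo else hi
        band <- conv_axis(ax2[[b]], k, 3L)
        out[[paste0(a, b, cc)]] <- image_volume(band, img$spacing, img$origin)
      }
    }
  }
  out[c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}

# coif1 decomposition filter bank (standard published taps)
coif1_dec_lo <- c(-0.015655728135791993, -0.07273261951252645,
                  0.3848648468648578, 0.8525720202116004,
                  0.3378976624574818, -0.07273261951252645)
coif1_dec_hi <- c(0.07273261951252645, 0.3378976624574818,
                  -0.8525720202116004, 0.3848648468648578,
                  0.07273261951252645, -0.015655728135791993)
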