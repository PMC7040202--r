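#' 3D image and mask containers
#'
#' An `image_volume` is a 3D array of scalar intensities (HU-like CT
#' attenuation values) plus the physical grid: per-axis voxel spacing in mm
#' and the physical coordinate of the first voxel (origin, mm). A
#' `mask_volume` is the binary volume of interest (VOI) on the same grid.
#' Voxel indexing is 0-based in physical-coordinate arithmetic
#' (coordinate of voxel (i,j,k) = origin + (i,j,k) * spacing with i,j,k
#' starting at 0), while R array subscripts remain 1-based as usual.
#'
#' @param voxels numeric 3D array of intensities.
#' @param spacing numeric length-3, per-axis voxel spacing in mm (all > 0).
#' @param origin numeric length-3, physical coordinate of the first voxel (mm).
#' @return An object of class `image_volume` (or `mask_volume`).
#' @examples
#' img <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 1))
#' dim(img$voxels)
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as_array3d(voxels)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("volume needs >= 1 voxel per axis", call. = FALSE)
  if (any(!is.finite(voxels))) stop("intensities must be finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @rdname image_volume
#' @details `mask_volume()` binarizes its input at > 0 and validates that the
#'   result contains only 0/1 values.
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as_array3d(voxels)
  if (any(!is.finite(voxels))) stop("mask values must be finite", call. = FALSE)
  vox <- array(as.numeric(voxels > 0), dim = dim(voxels))
  out <- image_volume(vox, spacing, origin)
  class(out) <- "mask_volume"
  out
}

as_array3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("voxel data must be a 3D array", call. = FALSE)
  storage.mode(x) <- "double"
  # strip dimnames and any foreign attributes (e.g. niftiImage) so volumes
  # compare as plain arrays
  array(as.vector(x), dim = dim(x))
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels > 0),
              paste(format(x$spacing, trim = TRUE), collapse = "x")))
  invisible(x)
}

#' Check that an image and mask share the same physical grid
#'
#' Image/mask pairs must be co-registered: identical array shape and
#' spacing/origin agreeing within `tol` mm per axis. The check is symmetric
#' in its two arguments.
#'
#' @param img an `image_volume`.
#' @param mask a `mask_volume` (or second `image_volume`).
#' @param tol per-axis tolerance in mm (default 1e-4).
#' @param require_foreground error when the mask has no foreground voxel.
#' @return invisibly `TRUE`; errors describe both grids on mismatch.
#' @export
validate_pair <- function(img, mask, tol = 1e-4, require_foreground = TRUE) {
  stopifnot(inherits(img, "image_volume") || inherits(img, "mask_volume"))
  if (!identical(dim(img$voxels), dim(mask$voxels)) ||
      any(abs(img$spacing - mask$spacing) > tol) ||
      any(abs(img$origin - mask$origin) > tol)) {
    stop(sprintf(
      paste0("image/mask grid mismatch: image %s @ (%s) mm origin (%s); ",
             "mask %s @ (%s) mm origin (%s)"),
      paste(dim(img$voxels), collapse = "x"),
      paste(format(img$spacing), collapse = ","),
      paste(format(img$origin), collapse = ","),
      paste(dim(mask$voxels), collapse = "x"),
      paste(format(mask$spacing), collapse = ","),
      paste(format(mask$origin), collapse = ",")), call. = FALSE)
  }
  if (require_foreground && inherits(mask, "mask_volume") &&
      sum(mask$voxels) == 0) {
    stop("empty VOI: mask has no foreground voxel", call. = FALSE)
  }
  invisible(TRUE)
}

voi_values <- function(img, mask) {
  img$voxels[mask$voxels > 0]
}

# bounding box of the foreground, as index ranges per axis
mask_bbox <- function(mask) {
  idx <- which(mask$voxels > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty VOI: mask has no foreground voxel", call. = FALSE)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

crop_to_bbox <- function(vol, bbox) {
  v <- vol$voxels[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2],
                  bbox$lo[3]:bbox$hi[3], drop = FALSE]
  out <- vol
  out$voxels <- v
  out$origin <- vol$origin + (bbox$lo - 1L) * vol$spacing
  out
}
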