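#' Resample an image/mask pair to an isotropic grid
#'
#' Both volumes are resampled onto a grid with the requested isotropic
#' spacing (default 1 mm), covering the same physical extent. Intensities are
#' interpolated trilinearly; the mask uses nearest-neighbour interpolation
#' and is re-binarized. When the input is already on the target grid, the
#' volumes are returned unchanged. 3D texture directions are only meaningful
#' on isotropic grids, which is why extraction resamples first.
#'
#' @param img an [image_volume].
#' @param mask the paired [mask_volume].
#' @param target isotropic voxel edge in mm (default 1).
#' @return list with elements `img` and `mask` on the new grid.
#' @export
resample_isotropic <- function(img, mask, target = 1) {
  validate_pair(img, mask)
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  if (all(abs(img$spacing - target) < 1e-9)) {
    return(list(img = img, mask = mask))
  }
  d <- dim(img$voxels)
  extent <- (d - 1L) * img$spacing
  nd <- pmax(1L, as.integer(floor(extent / target + 1e-9)) + 1L)
  newpos <- lapply(1:3, function(ax) (seq_len(nd[ax]) - 1) * target)
  vox_img <- interp3(img$voxels, img$spacing, newpos, method = "trilinear")
  vox_msk <- interp3(mask$voxels, mask$spacing, newpos, method = "nearest")
  new_img <- image_volume(vox_img, spacing = rep(target, 3), origin = img$origin)
  new_msk <- mask_volume(vox_msk > 0.5, spacing = rep(target, 3),
                         origin = img$origin)
  if (sum(new_msk$voxels) == 0) {
    stop("empty VOI: mask vanished after resampling", call. = FALSE)
  }
  list(img = new_img, mask = new_msk)
}

# interpolate a 3D array at the outer product of per-axis positions (given in
# physical mm relative to the first voxel)
interp3 <- function(arr, spacing, newpos, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  nd <- vapply(newpos, length, 1L)
  # continuous 0-based indices per axis
  f <- lapply(1:3, function(ax) newpos[[ax]] / spacing[ax])
  if (method == "nearest") {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(f[[ax]]) + 1, 1), d[ax]))
    g <- as.matrix(expand.grid(i = idx[[1]], j = idx[[2]], k = idx[[3]]))
    return(array(arr[g], dim = nd))
  }
  lo <- lapply(1:3, function(ax) {
    i0 <- floor(f[[ax]])
    i0 <- pmin(pmax(i0, 0), max(d[ax] - 2, 0))
    i0
  })
  w <- lapply(1:3, function(ax) pmin(pmax(f[[ax]] - lo[[ax]], 0), 1))
  i0 <- lapply(1:3, function(ax) as.integer(lo[[ax]]) + 1L)
  i1 <- lapply(1:3, function(ax) pmin(i0[[ax]] + 1L, d[ax]))
  gi <- expand.grid(a = seq_len(nd[1]), b = seq_len(nd[2]), c = seq_len(nd[3]))
  wx <- w[[1]][gi$a]; wy <- w[[2]][gi$b]; wz <- w[[3]][gi$c]
  at <- function(ix, iy, iz) {
    arr[cbind(ix[gi$a], iy[gi$b], iz[gi$c])]
  }
  v000 <- at(i0[[1]], i0[[2]], i0[[3]]); v100 <- at(i1[[1]], i0[[2]], i0[[3]])
  v010 <- at(i0[[1]], i1[[2]], i0[[3]]); v110 <- at(i1[[1]], i1[[2]], i0[[3]])
  v001 <- at(i0[[1]], i0[[2]], i1[[3]]); v101 <- at(i1[[1]], i0[[2]], i1[[3]])
  v011 <- at(i0[[1]], i1[[2]], i1[[3]]); v111 <- at(i1[[1]], i1[[2]], i1[[3]])
  out <- (1 - wz) * ((1 - wy) * ((1 - wx) * v000 + wx * v100) +
                     wy * ((1 - wx) * v010 + wx * v110)) +
         wz * ((1 - wy) * ((1 - wx) * v001 + wx * v101) +
               wy * ((1 - wx) * v011 + wx * v111))
  array(out, dim = nd)
}
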