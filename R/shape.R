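#' 3D shape features of a binary VOI
#'
#' Thirteen descriptors of the VOI geometry, independent of the intensity
#' distribution. Volume is voxel count times voxel volume (mm^3); surface
#' area (mm^2) comes from a marching-tetrahedra iso-surface mesh of the
#' lightly smoothed, supersampled mask (see the methods vignette for the
#' numerical choices and their measured bias). Axis lengths derive from the
#' eigenvalues of the second-moment (inertia) tensor of the voxel-center
#' point cloud, with axis length = 4*sqrt(eigenvalue). A single-voxel VOI is
#' degenerate: minor axes and elongation/flatness are defined as 0.
#'
#' Features: volume_mm3, surface_area_mm2, sphericity, compactness1,
#' compactness2, spherical_disproportion, maximum_3d_diameter,
#' major_axis_length, minor_axis_length, least_axis_length, elongation,
#' flatness, surface_volume_ratio.
#'
#' @param mask a [mask_volume].
#' @return named numeric vector of 13 features.
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  if (sum(mask$voxels) == 0) stop("empty VOI", call. = FALSE)
  mask <- crop_to_bbox(mask, mask_bbox(mask))  # all features translation-invariant
  sp <- mask$spacing
  nvox <- sum(mask$voxels > 0)
  volume <- nvox * prod(sp)
  area <- mesh_surface_area(mask)
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area
  compactness1 <- volume / (sqrt(pi) * area^1.5)
  compactness2 <- 36 * pi * volume^2 / area^3
  r_eq <- (3 * volume / (4 * pi))^(1 / 3)
  sph_disprop <- area / (4 * pi * r_eq^2)
  coords <- which(mask$voxels > 0, arr.ind = TRUE)
  phys <- sweep(coords - 1, 2, sp, `*`)
  maxdiam <- max_pairwise_distance(boundary_coords(mask))
  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes <- 4 * sqrt(ev)
    elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
    flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  } else {
    axes <- c(0, 0, 0); elongation <- 0; flatness <- 0
  }
  c(volume_mm3 = volume,
    surface_area_mm2 = area,
    sphericity = sphericity,
    compactness1 = compactness1,
    compactness2 = compactness2,
    spherical_disproportion = sph_disprop,
    maximum_3d_diameter = maxdiam,
    major_axis_length = axes[1],
    minor_axis_length = axes[2],
    least_axis_length = axes[3],
    elongation = elongation,
    flatness = flatness,
    surface_volume_ratio = area / volume)
}

# physical coordinates of foreground voxels that touch background (6-adjacency)
boundary_coords <- function(mask) {
  d0 <- dim(mask$voxels)
  m <- array(0, d0 + 2L)
  m[2:(d0[1] + 1L), 2:(d0[2] + 1L), 2:(d0[3] + 1L)] <- mask$voxels
  core <- m[2:(d0[1] + 1L), 2:(d0[2] + 1L), 2:(d0[3] + 1L), drop = FALSE]
  nb <- m[1:d0[1], 2:(d0[2] + 1L), 2:(d0[3] + 1L), drop = FALSE] +
        m[3:(d0[1] + 2L), 2:(d0[2] + 1L), 2:(d0[3] + 1L), drop = FALSE] +
        m[2:(d0[1] + 1L), 1:d0[2], 2:(d0[3] + 1L), drop = FALSE] +
        m[2:(d0[1] + 1L), 3:(d0[2] + 2L), 2:(d0[3] + 1L), drop = FALSE] +
        m[2:(d0[1] + 1L), 2:(d0[2] + 1L), 1:d0[3], drop = FALSE] +
        m[2:(d0[1] + 1L), 2:(d0[2] + 1L), 3:(d0[3] + 2L), drop = FALSE]
  idx <- which(core > 0 & nb < 6, arr.ind = TRUE)
  sweep(idx - 1, 2, mask$spacing, `*`)
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(0)
  # exact pruning: a pair at distance d has r_i + r_j >= d (radii from the
  # centroid), so with lower bound d0 and R = max r, any point with
  # r < d0 - R cannot belong to the farthest pair
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  r <- sqrt(rowSums(cen^2))
  R <- max(r)
  far <- which.max(r)
  d0 <- sqrt(max(rowSums(sweep(pts, 2, pts[far, ])^2)))
  sub <- pts[r >= d0 - R - 1e-9, , drop = FALSE]
  sq <- rowSums(sub^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(sub)
  max(d0, sqrt(max(d2, 0)))
}
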