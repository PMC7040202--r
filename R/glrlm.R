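#' Gray-level run-length matrices and features
#'
#' A run is a maximal set of collinear VOI voxels sharing one gray level
#' along a scan direction. `glrlm_build()` counts runs by gray level and
#' length for one of the 13 unique 3D directions; runs break at VOI gaps and
#' grid borders. `glrlm_features()` computes 12 run-length statistics per
#' direction and averages across non-empty directions. Short run high
#' gray-level emphasis (SRHGLE) is
#' \eqn{(1/N_r) \sum_{i,l} r(i,l)\, i^2 / l^2}.
#'
#' @param dis a discretization as returned by [discretize].
#' @param direction integer length-3 offset, components in -1/0/1.
#' @return `glrlm_build`: list with `r` (Ng x Lmax run-count matrix),
#'   `n_runs`, `n_voxels`; `glrlm_features`: named numeric vector of 12
#'   features.
#' @export
glrlm_build <- function(dis, direction) {
  lev <- dis$levels
  ng <- dis$n_levels
  d <- dim(lev)
  dir <- as.integer(direction)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  nvox <- nrow(idx)
  if (nvox == 0L) {
    return(list(r = matrix(0L, ng, 1L), n_runs = 0L, n_voxels = 0L))
  }
  vals <- lev[!is.na(lev)]
  # parameter along the scan line and an id for the line itself
  ax <- which(dir != 0)[1]
  t <- idx[, ax] * dir[ax]
  line <- idx - outer(t, dir)
  key <- (line[, 1] + d[1]) + (line[, 2] + d[2]) * (3L * d[1]) +
    (line[, 3] + d[3]) * (9L * d[1] * d[2])
  o <- order(key, t)
  key <- key[o]; t <- t[o]; v <- vals[o]
  newrun <- c(TRUE, key[-1] != key[-nvox] | t[-1] != t[-nvox] + 1L |
                v[-1] != v[-nvox])
  run_id <- cumsum(newrun)
  run_len <- tabulate(run_id)
  run_lev <- v[newrun]
  lmax <- max(run_len)
  counts <- tabulate((run_len - 1L) * ng + run_lev, nbins = ng * lmax)
  list(r = matrix(counts, ng, lmax), n_runs = length(run_len),
       n_voxels = nvox)
}

#' @rdname glrlm_build
#' @param glrlms list of GLRLMs from [glrlm_build], one per direction.
#' @export
glrlm_features <- function(glrlms) {
  keep <- Filter(function(g) g$n_runs > 0L, glrlms)
  if (length(keep) == 0L) stop("all GLRLM directions are empty", call. = FALSE)
  per <- vapply(keep, glrlm_features_one, numeric(length(glrlm_feature_names)))
  rowMeans(per)
}

glrlm_feature_names <- c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "run_length_nonuniformity", "run_percentage",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis",
  "gray_level_variance")

glrlm_features_one <- function(g) {
  r <- g$r
  nr <- g$n_runs
  np <- g$n_voxels
  i <- row(r); l <- col(r)
  ri <- rowSums(r); rl <- colSums(r)
  lev <- seq_len(nrow(r))
  mu <- sum(lev * ri) / nr
  c(short_run_emphasis = sum(r / l^2) / nr,
    long_run_emphasis = sum(r * l^2) / nr,
    gray_level_nonuniformity = sum(ri^2) / nr,
    run_length_nonuniformity = sum(rl^2) / nr,
    run_percentage = nr / np,
    low_gray_level_run_emphasis = sum(r / i^2) / nr,
    high_gray_level_run_emphasis = sum(r * i^2) / nr,
    short_run_low_gray_level_emphasis = sum(r / (i^2 * l^2)) / nr,
    short_run_high_gray_level_emphasis = sum(r * i^2 / l^2) / nr,
    long_run_low_gray_level_emphasis = sum(r * l^2 / i^2) / nr,
    long_run_high_gray_level_emphasis = sum(r * i^2 * l^2) / nr,
    gray_level_variance = sum((i - mu)^2 * r) / nr)
}
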