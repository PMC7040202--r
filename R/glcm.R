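#' Gray-level co-occurrence matrices and features
#'
#' `glcm_directions()` returns the 13 unique 3D voxel offsets (26-connected
#' neighbourhood up to sign). `glcm_build()` counts co-occurring gray-level
#' pairs at one offset, accumulating both orientations when `symmetric`, and
#' normalizes to probabilities. `glcm_features()` computes 24 Haralick-family
#' statistics per direction and averages them across directions; directions
#' with no valid voxel pair are excluded from the average.
#'
#' Cluster shade is the third central co-moment
#' \eqn{\sum_{i,j} (i + j - \mu_i - \mu_j)^3 p(i,j)} (large magnitude =
#' asymmetric co-occurrence distribution); inverse variance is
#' \eqn{\sum_{i \ne j} p(i,j)/(i-j)^2}.
#'
#' @param dis a discretization as returned by [discretize].
#' @param direction integer length-3 offset, components in -1/0/1.
#' @param delta offset multiplier (voxels, default 1).
#' @param symmetric accumulate the transposed pairs too (default TRUE).
#' @return `glcm_build`: list with `p` (Ng x Ng probability matrix) and
#'   `n_pairs`; `glcm_features`: named numeric vector of 24 features.
#' @export
glcm_build <- function(dis, direction, delta = 1L, symmetric = TRUE) {
  lev <- dis$levels
  ng <- dis$n_levels
  d <- dim(lev)
  off <- as.integer(direction) * as.integer(delta)
  rng <- lapply(1:3, function(ax) {
    if (off[ax] >= 0) seq_len(d[ax] - off[ax]) else seq.int(1L - off[ax], d[ax])
  })
  if (any(vapply(rng, length, 1L) < 1L)) {
    return(list(p = matrix(0, ng, ng), n_pairs = 0L))
  }
  a <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  i <- a[ok]; j <- b[ok]
  n <- length(i)
  if (n == 0L) return(list(p = matrix(0, ng, ng), n_pairs = 0L))
  counts <- tabulate((j - 1L) * ng + i, nbins = ng * ng)
  cm <- matrix(counts, ng, ng)
  if (symmetric) cm <- cm + t(cm)
  list(p = cm / sum(cm), n_pairs = as.integer(n))
}

#' @rdname glcm_build
#' @export
glcm_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
}

#' @rdname glcm_build
#' @param glcms list of GLCMs from [glcm_build], one per direction.
#' @export
glcm_features <- function(glcms) {
  keep <- Filter(function(g) g$n_pairs > 0L, glcms)
  if (length(keep) == 0L) stop("all GLCM directions are empty", call. = FALSE)
  per <- vapply(keep, function(g) glcm_features_one(g$p),
                numeric(length(glcm_feature_names)))
  rowMeans(per)
}

glcm_feature_names <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_entropy",
  "difference_variance", "dissimilarity", "joint_energy", "joint_entropy",
  "inverse_difference", "inverse_difference_moment",
  "inverse_difference_moment_normalized", "inverse_difference_normalized",
  "imc1", "imc2", "inverse_variance", "maximum_probability", "sum_average",
  "sum_entropy", "sum_variance", "sum_of_squares")

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  lev <- seq_len(ng)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  # sum / difference marginals (grouped sums over the anti-/diagonals)
  ks <- 2:(2 * ng)
  psum <- as.vector(rowsum(as.vector(p), group = as.vector(i + j)))
  kd <- 0:(ng - 1)
  pdiff <- as.vector(rowsum(as.vector(p), group = as.vector(abs(i - j))))
  l2 <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  hx <- l2(px); hy <- l2(py); hxy <- l2(p)
  pq <- outer(px, py)
  sel <- p > 0
  hxy1 <- -sum(p[sel] * log2(pmax(pq[sel], .Machine$double.xmin)))
  hxy2 <- l2(pq)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  cs <- i + j - mux - muy
  da <- sum(kd * pdiff)
  sa <- sum(ks * psum)
  offd <- i != j
  c(autocorrelation = sum(i * j * p),
    joint_average = mux,
    cluster_prominence = sum(cs^4 * p),
    cluster_shade = sum(cs^3 * p),
    cluster_tendency = sum(cs^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0,
    difference_entropy = l2(pdiff),
    difference_variance = sum((kd - da)^2 * pdiff),
    dissimilarity = sum(abs(i - j) * p),
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    inverse_difference = sum(p / (1 + abs(i - j))),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inverse_difference_moment_normalized = sum(p / (1 + ((i - j) / ng)^2)),
    inverse_difference_normalized = sum(p / (1 + abs(i - j) / ng)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum(p[offd] / (i[offd] - j[offd])^2),
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = l2(psum),
    sum_variance = sum((ks - sa)^2 * psum),
    sum_of_squares = sum((i - mux)^2 * p))
}
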