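# Independent, deliberately naive re-implementations used as test oracles.
# Everything here is scalar-looped and written from the textbook definitions,
# sharing no code with the package internals.

# --- gray-level co-occurrence ------------------------------------------------

oracle_glcm <- function(lev, dir, delta = 1L, ng) {
  d <- dim(lev)
  cm <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    x2 <- x + dir[1] * delta; y2 <- y + dir[2] * delta; z2 <- z + dir[3] * delta
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    b <- lev[x2, y2, z2]
    if (is.na(b)) next
    cm[a, b] <- cm[a, b] + 1
    cm[b, a] <- cm[b, a] + 1
  }
  cm
}

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) { sx2 <- sx2 + (i - mux)^2 * px[i]; sy2 <- sy2 + (i - muy)^2 * py[i] }
  psum <- numeric(2 * ng); pdiff <- numeric(ng)  # pdiff index k+1 for k = 0..ng-1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  ent <- function(v) { s <- 0; for (q in v) if (q > 0) s <- s - q * log2(q); s }
  hx <- ent(px); hy <- ent(py); hxy <- ent(as.vector(p))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(max(px[i] * py[j], .Machine$double.xmin))
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  }
  acc <- function(f) { s <- 0; for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j) * p[i, j]; s }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pdiff[k + 1]
  dv <- 0; for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pdiff[k + 1]
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * psum[k]
  iv <- 0
  for (i in 1:ng) for (j in 1:ng) if (i != j) iv <- iv + p[i, j] / (i - j)^2
  corr <- if (sx2 > 0 && sy2 > 0)
    (acc(function(i, j) i * j) - mux * muy) / sqrt(sx2 * sy2) else 0
  c(autocorrelation = acc(function(i, j) i * j),
    joint_average = mux,
    cluster_prominence = acc(function(i, j) (i + j - mux - muy)^4),
    cluster_shade = acc(function(i, j) (i + j - mux - muy)^3),
    cluster_tendency = acc(function(i, j) (i + j - mux - muy)^2),
    contrast = acc(function(i, j) (i - j)^2),
    correlation = corr,
    difference_entropy = ent(pdiff),
    difference_variance = dv,
    dissimilarity = acc(function(i, j) abs(i - j)),
    joint_energy = sum(p * p),
    joint_entropy = hxy,
    inverse_difference = acc(function(i, j) 1 / (1 + abs(i - j))),
    inverse_difference_moment = acc(function(i, j) 1 / (1 + (i - j)^2)),
    inverse_difference_moment_normalized = acc(function(i, j) 1 / (1 + ((i - j) / ng)^2)),
    inverse_difference_normalized = acc(function(i, j) 1 / (1 + abs(i - j) / ng)),
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)),
    inverse_variance = iv,
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = ent(psum),
    sum_variance = sv,
    sum_of_squares = acc(function(i, j) (i - mux)^2))
}

# --- gray-level run length ---------------------------------------------------

oracle_glrlm <- function(lev, dir, ng) {
  d <- dim(lev)
  inb <- function(q) all(q >= 1) && all(q <= d)
  runs <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    v <- lev[x, y, z]
    if (is.na(v)) next
    prev <- c(x, y, z) - dir
    starts <- !inb(prev) || is.na(lev[prev[1], prev[2], prev[3]]) ||
      lev[prev[1], prev[2], prev[3]] != v
    if (!starts) next
    len <- 1L
    nxt <- c(x, y, z) + dir
    while (inb(nxt) && !is.na(lev[nxt[1], nxt[2], nxt[3]]) &&
           lev[nxt[1], nxt[2], nxt[3]] == v) {
      len <- len + 1L
      nxt <- nxt + dir
    }
    runs[[length(runs) + 1L]] <- c(v, len)
  }
  if (length(runs) == 0L) return(matrix(0, ng, 1))
  lmax <- max(vapply(runs, `[`, 0, 2))
  r <- matrix(0, ng, lmax)
  for (rr in runs) r[rr[1], rr[2]] <- r[rr[1], rr[2]] + 1
  r
}

oracle_glrlm_features <- function(r, n_voxels) {
  ng <- nrow(r); lmax <- ncol(r)
  nr <- sum(r)
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (l in 1:lmax) s <- s + f(i, l) * r[i, l]
    s / nr
  }
  ri <- numeric(ng); rl <- numeric(lmax)
  for (i in 1:ng) for (l in 1:lmax) { ri[i] <- ri[i] + r[i, l]; rl[l] <- rl[l] + r[i, l] }
  mu <- 0; for (i in 1:ng) mu <- mu + i * ri[i] / nr
  c(short_run_emphasis = acc(function(i, l) 1 / l^2),
    long_run_emphasis = acc(function(i, l) l^2),
    gray_level_nonuniformity = sum(ri^2) / nr,
    run_length_nonuniformity = sum(rl^2) / nr,
    run_percentage = nr / n_voxels,
    low_gray_level_run_emphasis = acc(function(i, l) 1 / i^2),
    high_gray_level_run_emphasis = acc(function(i, l) i^2),
    short_run_low_gray_level_emphasis = acc(function(i, l) 1 / (i^2 * l^2)),
    short_run_high_gray_level_emphasis = acc(function(i, l) i^2 / l^2),
    long_run_low_gray_level_emphasis = acc(function(i, l) l^2 / i^2),
    long_run_high_gray_level_emphasis = acc(function(i, l) i^2 * l^2),
    gray_level_variance = acc(function(i, l) (i - mu)^2))
}

# averaged-over-directions oracle for a discretization (matches the package's
# 13-direction protocol, recomputed from the naive builders above)
oracle_texture_features <- function(lev, ng, delta = 1L) {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  nvox <- sum(!is.na(lev))
  gl <- NULL; gr <- NULL
  for (k in seq_len(nrow(dirs))) {
    cm <- oracle_glcm(lev, dirs[k, ], delta, ng)
    if (sum(cm) > 0) gl <- rbind(gl, oracle_glcm_features(cm / sum(cm)))
    r <- oracle_glrlm(lev, dirs[k, ], ng)
    if (sum(r) > 0) gr <- rbind(gr, oracle_glrlm_features(r, nvox))
  }
  list(glcm = colMeans(gl), glrlm = colMeans(gr))
}

# --- survival ----------------------------------------------------------------

oracle_cindex <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# standard (rho = 0) two-group log-rank chi-square from the textbook formula
oracle_logrank <- function(groups, time, event) {
  g <- as.integer(factor(groups))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at <- time >= t
    nj <- sum(at); n1 <- sum(at & g == 1)
    dj <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + dj * n1 / nj
    if (nj > 1) V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  (O - E)^2 / V
}

# --- small fixture builders --------------------------------------------------

mk_img <- function(values, dim3, spacing = c(1, 1, 1)) {
  image_volume(array(values, dim = dim3), spacing = spacing)
}

mk_ball_mask <- function(d, radius, spacing = c(1, 1, 1)) {
  center <- (d - 1) * spacing / 2
  g <- expand.grid(x = ((seq_len(d[1]) - 1) * spacing[1] - center[1]),
                   y = ((seq_len(d[2]) - 1) * spacing[2] - center[2]),
                   z = ((seq_len(d[3]) - 1) * spacing[3] - center[3]))
  mask_volume(array(g$x^2 + g$y^2 + g$z^2 <= radius^2, dim = d),
              spacing = spacing)
}

mk_ellipsoid_mask <- function(d, semi, spacing = c(1, 1, 1)) {
  center <- (d - 1) * spacing / 2
  g <- expand.grid(x = ((seq_len(d[1]) - 1) * spacing[1] - center[1]) / semi[1],
                   y = ((seq_len(d[2]) - 1) * spacing[2] - center[2]) / semi[2],
                   z = ((seq_len(d[3]) - 1) * spacing[3] - center[3]) / semi[3])
  mask_volume(array(g$x^2 + g$y^2 + g$z^2 <= 1, dim = d), spacing = spacing)
}

mk_clinical <- function(n, time, event, seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             sex = sample(c("male", "female"), n, TRUE),
             age_years = round(runif(n, 30, 80)),
             smoking = sample(c("smoker", "nonsmoker"), n, TRUE),
             pfs_days = time, event = as.integer(event),
             cohort_label = "test", stringsAsFactors = FALSE)
}
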