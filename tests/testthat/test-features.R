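test_that("first-order features match hand-computed values on {1,2,3,4}", {
  img <- mk_img(c(1, 2, 3, 4), c(4, 1, 1))
  msk <- mask_volume(array(1, c(4, 1, 1)))
  f <- first_order_features(img, msk)
  expect_equal(f[["minimum"]], 1)
  expect_equal(f[["maximum"]], 4)
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["median"]], 2.5)
  expect_equal(f[["range"]], 3)
  expect_equal(f[["variance"]], 1.25)            # population convention
  expect_equal(f[["standard_deviation"]], sqrt(1.25))
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 2.5625 / 1.25^2) # non-excess
  expect_equal(f[["energy"]], 30)
  expect_equal(f[["entropy"]], 2)                # 4 equi-probable bins
  expect_equal(f[["uniformity"]], 0.25)
  expect_equal(f[["mean_absolute_deviation"]], 1)
  expect_equal(f[["root_mean_square"]], sqrt(7.5))
})

test_that("percentiles use linear interpolation (R type-7 quantiles)", {
  img <- mk_img(1:10, c(10, 1, 1))
  msk <- mask_volume(array(1, c(10, 1, 1)))
  f <- first_order_features(img, msk)
  expect_equal(f[["percentile_10"]], 1.9)
  expect_equal(f[["percentile_90"]], 9.1)
  expect_equal(f[["median"]], 5.5)
})

test_that("constant VOI has zero standardized moments, not NaN", {
  img <- mk_img(rep(7, 8), c(2, 2, 2))
  msk <- mask_volume(array(1, c(2, 2, 2)))
  f <- first_order_features(img, msk)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 0)
  expect_equal(f[["variance"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["uniformity"]], 1)
})

test_that("discretization is monotone with min -> 1 and max -> n_levels", {
  set.seed(5)
  img <- mk_img(rnorm(60), c(5, 4, 3))
  msk <- mask_volume(array(rbinom(60, 1, 0.7), c(5, 4, 3)))
  dis <- discretize(img, msk, n_levels = 32)
  vals <- img$voxels[msk$voxels > 0]
  lev <- dis$levels[msk$voxels > 0]
  expect_true(all(is.na(dis$levels[msk$voxels == 0])))
  expect_equal(lev[which.min(vals)], 1L)
  expect_equal(lev[which.max(vals)], 32L)
  expect_true(all(lev >= 1 & lev <= 32))
  ord <- order(vals)
  expect_true(all(diff(lev[ord]) >= 0))
  expect_false(dis$constant)

  cst <- discretize(mk_img(rep(3, 60), c(5, 4, 3)), msk, 32)
  expect_true(cst$constant)
  expect_true(all(cst$levels[msk$voxels > 0] == 1L))
})

test_that("shape features are exact on a 10mm cube where analytic", {
  msk <- mask_volume(array(1, c(10, 10, 10)))
  s <- shape_features(msk)
  expect_equal(s[["volume_mm3"]], 1000)
  expect_equal(s[["maximum_3d_diameter"]], 9 * sqrt(3), tolerance = 1e-12)
  # mesh rounds the cube's corners slightly: area close to, never far from, 600
  expect_gt(s[["surface_area_mm2"]], 500)
  expect_lt(s[["surface_area_mm2"]], 615)
  expect_equal(s[["surface_volume_ratio"]],
               s[["surface_area_mm2"]] / 1000, tolerance = 1e-12)
  # cube has equal principal axes
  expect_equal(s[["elongation"]], 1, tolerance = 1e-10)
  expect_equal(s[["flatness"]], 1, tolerance = 1e-10)
})

test_that("digital ball has near-unit sphericity and consistent compactness", {
  msk <- mk_ball_mask(c(24, 24, 24), radius = 8)
  s <- shape_features(msk)
  expect_gt(s[["sphericity"]], 0.93)
  expect_lte(s[["sphericity"]], 1.005)
  expect_equal(s[["spherical_disproportion"]], 1 / s[["sphericity"]],
               tolerance = 1e-10)
  expect_equal(s[["compactness2"]], s[["sphericity"]]^3, tolerance = 1e-10)
  vol_true <- 4 / 3 * pi * 8^3
  expect_lt(abs(s[["volume_mm3"]] - vol_true) / vol_true, 0.1)
  expect_lt(abs(s[["maximum_3d_diameter"]] - 16) / 16, 0.1)
})

test_that("principal axes recover ellipsoid semi-axes", {
  msk <- mk_ellipsoid_mask(c(36, 26, 18), semi = c(8, 5, 3))
  s <- shape_features(msk)
  # uniform solid ellipsoid: eigenvalue = a^2/5, axis length = 4a/sqrt(5)
  expect_lt(abs(s[["major_axis_length"]] - 4 * 8 / sqrt(5)) / (4 * 8 / sqrt(5)), 0.08)
  expect_lt(abs(s[["minor_axis_length"]] - 4 * 5 / sqrt(5)) / (4 * 5 / sqrt(5)), 0.08)
  expect_lt(abs(s[["least_axis_length"]] - 4 * 3 / sqrt(5)) / (4 * 3 / sqrt(5)), 0.12)
  expect_lt(abs(s[["elongation"]] - 5 / 8), 0.06)
  expect_lt(abs(s[["flatness"]] - 3 / 8), 0.06)
})

test_that("shape features are translation-invariant and intensity-free", {
  m1 <- array(0, c(12, 12, 12)); m1[3:7, 4:8, 5:9] <- 1
  m2 <- array(0, c(12, 12, 12)); m2[6:10, 2:6, 3:7] <- 1
  s1 <- shape_features(mask_volume(m1))
  s2 <- shape_features(mask_volume(m2))
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_error(shape_features(mask_volume(array(0, c(4, 4, 4)))), "empty VOI")
})

test_that("GLCM counts match the worked 2x2 example", {
  lev <- array(c(1L, 2L, 1L, 2L), c(2, 2, 1))
  dis <- list(levels = lev, n_levels = 2L, constant = FALSE)
  gx <- glcm_build(dis, c(1, 0, 0))
  expect_equal(gx$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(gx$n_pairs, 2L)
  gy <- glcm_build(dis, c(0, 1, 0))
  expect_equal(gy$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  gz <- glcm_build(dis, c(0, 0, 1))
  expect_equal(gz$n_pairs, 0L)
  f <- glcm_features(list(gx))
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["cluster_shade"]], 0)
  expect_equal(f[["maximum_probability"]], 0.5)
  expect_equal(f[["joint_energy"]], 0.5)
})

test_that("cluster shade flips sign under gray-level reflection", {
  set.seed(11)
  ng <- 6L
  lev <- array(sample.int(ng, 80, replace = TRUE), c(5, 4, 4))
  lev[sample(80, 15)] <- NA
  dis1 <- list(levels = lev, n_levels = ng, constant = FALSE)
  dis2 <- list(levels = ng + 1L - lev, n_levels = ng, constant = FALSE)
  dirs <- glcm_directions()
  f1 <- glcm_features(lapply(seq_len(nrow(dirs)),
                             function(k) glcm_build(dis1, dirs[k, ])))
  f2 <- glcm_features(lapply(seq_len(nrow(dirs)),
                             function(k) glcm_build(dis2, dirs[k, ])))
  expect_equal(f1[["cluster_shade"]], -f2[["cluster_shade"]], tolerance = 1e-12)
  expect_equal(f1[["contrast"]], f2[["contrast"]], tolerance = 1e-12)
  expect_equal(f1[["joint_entropy"]], f2[["joint_entropy"]], tolerance = 1e-12)
})

test_that("direction-averaged texture features are axis-permutation invariant", {
  set.seed(13)
  ng <- 5L
  lev <- array(sample.int(ng, 120, replace = TRUE), c(6, 5, 4))
  lev[sample(120, 20)] <- NA
  run_feats <- function(levels) {
    dis <- list(levels = levels, n_levels = ng, constant = FALSE)
    dirs <- glcm_directions()
    list(glcm = glcm_features(lapply(seq_len(nrow(dirs)),
                                     function(k) glcm_build(dis, dirs[k, ]))),
         glrlm = glrlm_features(lapply(seq_len(nrow(dirs)),
                                       function(k) glrlm_build(dis, dirs[k, ]))))
  }
  a <- run_feats(lev)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2), c(2, 3, 1))) {
    b <- run_feats(aperm(lev, perm))
    expect_equal(a$glcm, b$glcm, tolerance = 1e-12)
    expect_equal(a$glrlm, b$glrlm, tolerance = 1e-12)
  }
})

test_that("GLRLM matches hand-counted runs", {
  # single line [2,2,2]: one run of level 2, length 3
  dis <- list(levels = array(2L, c(3, 1, 1)), n_levels = 2L, constant = FALSE)
  g <- glrlm_build(dis, c(1, 0, 0))
  expect_equal(g$n_runs, 1L)
  expect_equal(g$r[2, 3], 1L)
  f <- glrlm_features(list(g))
  expect_equal(f[["short_run_emphasis"]], 1 / 9)
  expect_equal(f[["short_run_high_gray_level_emphasis"]], 4 / 9)
  expect_equal(f[["run_percentage"]], 1 / 3)
  expect_equal(f[["high_gray_level_run_emphasis"]], 4)

  # [1,1,2]: runs (level 1, len 2) and (level 2, len 1)
  dis2 <- list(levels = array(c(1L, 1L, 2L), c(3, 1, 1)), n_levels = 2L,
               constant = FALSE)
  f2 <- glrlm_features(list(glrlm_build(dis2, c(1, 0, 0))))
  expect_equal(f2[["short_run_high_gray_level_emphasis"]], (1 / 4 + 4) / 2)
  expect_equal(f2[["run_percentage"]], 2 / 3)

  # runs break across VOI gaps
  dis3 <- list(levels = array(c(1L, NA, 1L), c(3, 1, 1)), n_levels = 2L,
               constant = FALSE)
  expect_equal(glrlm_build(dis3, c(1, 0, 0))$n_runs, 2L)
})

test_that("texture features equal the brute-force oracle on random VOIs", {
  set.seed(17)
  for (rep in 1:12) {
    d <- c(sample(2:6, 1), sample(2:6, 1), sample(2:6, 1))
    ng <- sample(3:8, 1)
    lev <- array(sample.int(ng, prod(d), replace = TRUE), d)
    if (rep > 4) lev[sample(prod(d), ceiling(prod(d) / 4))] <- NA
    if (all(is.na(lev))) next
    dis <- list(levels = lev, n_levels = ng, constant = FALSE)
    dirs <- glcm_directions()
    got_glcm <- glcm_features(lapply(seq_len(nrow(dirs)),
                                     function(k) glcm_build(dis, dirs[k, ])))
    got_glrlm <- glrlm_features(lapply(seq_len(nrow(dirs)),
                                       function(k) glrlm_build(dis, dirs[k, ])))
    ora <- oracle_texture_features(lev, ng)
    expect_equal(got_glcm, ora$glcm[names(got_glcm)], tolerance = 1e-12)
    expect_equal(got_glrlm, ora$glrlm[names(got_glrlm)], tolerance = 1e-12)
  }
})

test_that("wavelet bands respond correctly to a constant image", {
  img <- image_volume(array(25, c(10, 10, 10)))
  bands <- wavelet_channels(img)
  expect_named(bands, c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH"))
  expect_equal(max(abs(bands$HHH$voxels)), 0, tolerance = 1e-10)
  expect_equal(max(abs(bands$HLL$voxels)), 0, tolerance = 1e-10)
  # low-pass gain is sqrt(2) per axis
  expect_equal(bands$LLL$voxels[5, 5, 5], 25 * 2^1.5, tolerance = 1e-9)
  # undecimated: all bands keep the grid
  for (b in bands) expect_equal(dim(b$voxels), c(10, 10, 10))
})

test_that("gaussian smoothing preserves constants and local means", {
  arr <- array(3.5, c(6, 6, 6))
  sm <- radsig:::smooth_gaussian(arr, c(1, 1, 1))
  expect_equal(sm, arr, tolerance = 1e-12)
})

test_that("isotropic resampling produces the expected grid and values", {
  set.seed(19)
  vox <- array(0, c(10, 6, 6))
  for (i in 1:10) vox[i, , ] <- i          # linear ramp along x
  img <- image_volume(vox, spacing = c(2, 1, 1))
  m <- array(0, c(10, 6, 6)); m[4:7, 2:5, 2:5] <- 1
  msk <- mask_volume(m, spacing = c(2, 1, 1))
  rs <- resample_isotropic(img, msk, 1)
  expect_equal(rs$img$spacing, c(1, 1, 1))
  expect_equal(dim(rs$img$voxels)[1], 19)
  # trilinear interpolation reproduces a linear ramp exactly
  expect_equal(rs$img$voxels[2, 3, 3], 1.5, tolerance = 1e-12)
  expect_equal(rs$img$voxels[19, 3, 3], 10, tolerance = 1e-12)
  # mask volume in mm^3 approximately preserved
  expect_lt(abs(sum(rs$mask$voxels) * 1 - sum(m) * 2) / (sum(m) * 2), 0.15)
  # identity fast path
  rs2 <- resample_isotropic(rs$img, rs$mask, 1)
  expect_identical(rs2$img$voxels, rs$img$voxels)
})

test_that("registry defines 481 uniquely named features across 4 families", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 481)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(sum(reg$family == "shape"), 13)
  expect_equal(sum(reg$family == "first-order"), 9 * 16)
  expect_equal(sum(reg$family == "GLCM"), 9 * 24)
  expect_equal(sum(reg$family == "GLRLM"), 9 * 12)
  expect_equal(length(unique(reg$channel)), 9)  # original + 8 wavelet bands
  reg0 <- feature_registry(wavelet = FALSE)
  expect_equal(nrow(reg0), 13 + 52)
})

test_that("extract_all returns finite registry-ordered features, deterministically", {
  base <- phantom_params(shape = c(20, 20, 16), semi_axes = c(5, 4.5, 4))
  ph <- generate_phantom(base, seed = 2)
  v1 <- extract_all(ph$img, ph$mask)
  v2 <- extract_all(ph$img, ph$mask)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_equal(length(v1), 481)
  expect_identical(names(v1), feature_registry()$name)
  expect_true(all(is.finite(v1)))
  expect_true(v1[["original_firstorder_variance"]] > 0)
})

test_that("texture features ignore intensities outside the VOI", {
  base <- phantom_params(shape = c(18, 18, 14), semi_axes = c(4.5, 4, 3.5))
  ph <- generate_phantom(base, seed = 5)
  img2 <- ph$img
  img2$voxels[ph$mask$voxels == 0] <- img2$voxels[ph$mask$voxels == 0] + 500
  cfg <- extraction_config(wavelet = FALSE)
  f1 <- extract_all(ph$img, ph$mask, cfg)
  f2 <- extract_all(img2, ph$mask, cfg)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-12)
})

test_that("extraction failures identify the patient", {
  img <- image_volume(array(1, c(4, 4, 4)))
  msk <- mask_volume(array(0, c(4, 4, 4)))
  expect_error(extract_all(img, msk, patient_id = "P042"), "empty VOI")
})
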