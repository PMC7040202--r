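#' Synthetic CT phantom parameters
#'
#' Parameters of a single ellipsoidal tumor phantom on a CT-like grid. The
#' tumor interior is `base` plus a stationary, isotropic correlated Gaussian
#' texture field with variance `sigma2` (HU^2) and correlation length
#' `corr_len` (mm, the Gaussian smoothing width), optionally skewed by the
#' monotone exponential tilt controlled by `skew` (0 = symmetric; positive
#' values give a right-skewed intensity distribution, which cluster-shade
#' type features respond to). The background is `background` plus white
#' noise.
#'
#' @param shape grid size per axis (voxels).
#' @param spacing voxel spacing per axis (mm).
#' @param semi_axes tumor ellipsoid semi-axes (mm); must fit inside the grid.
#' @param background background intensity level (HU-like).
#' @param noise_sd background white-noise standard deviation.
#' @param base tumor base intensity.
#' @param sigma2 tumor texture variance (>= 0).
#' @param corr_len texture correlation length in mm (> 0).
#' @param skew skewness control (unitless, 0 = none).
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(32L, 32L, 24L), spacing = c(1, 1, 1),
                           semi_axes = c(8, 7, 6), background = -800,
                           noise_sd = 20, base = 40, sigma2 = 100,
                           corr_len = 2, skew = 0) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(spacing) == 3L,
            all(spacing > 0), length(semi_axes) == 3L, all(semi_axes > 0),
            sigma2 >= 0, corr_len > 0, noise_sd >= 0)
  extent <- (shape - 1) * spacing / 2
  if (any(semi_axes >= extent)) {
    stop("tumor ellipsoid does not fit inside the grid", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 semi_axes = as.numeric(semi_axes),
                 background = background, noise_sd = noise_sd, base = base,
                 sigma2 = sigma2, corr_len = corr_len, skew = skew),
            class = "phantom_params")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Generate one synthetic tumor phantom
#'
#' Returns an image/mask pair: an ellipsoidal VOI centered in the grid,
#' textured tumor interior (correlated Gaussian field, optional skew tilt,
#' rescaled to exactly the requested marginal variance in expectation) over a
#' noisy background. Bit-identical output for identical `(params, seed)`.
#'
#' @param params a [phantom_params].
#' @param seed integer seed.
#' @return list with elements `img` ([image_volume]) and `mask`
#'   ([mask_volume]).
#' @export
generate_phantom <- function(params, seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(seed, {
    d <- params$shape
    sp <- params$spacing
    center <- (d - 1) * sp / 2
    ax <- lapply(1:3, function(k) ((seq_len(d[k]) - 1) * sp[k] - center[k]) /
                   params$semi_axes[k])
    g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
    inside <- array(g$x^2 + g$y^2 + g$z^2 <= 1, dim = d)
    vox <- params$background +
      array(stats::rnorm(prod(d), sd = params$noise_sd), dim = d)
    tumor <- params$base + texture_field(d, sp, params$sigma2,
                                         params$corr_len, params$skew)
    vox[inside] <- tumor[inside]
    list(img = image_volume(vox, spacing = sp),
         mask = mask_volume(inside, spacing = sp))
  })
}

# correlated (optionally skewed) Gaussian field with marginal variance sigma2
texture_field <- function(d, spacing, sigma2, corr_len, skew) {
  if (sigma2 == 0) return(array(0, dim = d))
  w <- array(stats::rnorm(prod(d)), dim = d)
  norm2 <- 1
  for (axk in 1:3) {
    sig_vox <- corr_len / spacing[axk]
    k <- gaussian_kernel_1d(sig_vox)
    w <- conv_axis(w, k, axk, anchor = (length(k) + 1L) / 2)
    norm2 <- norm2 * sum(k^2)
  }
  z <- w / sqrt(norm2)  # marginal ~ N(0, 1)
  if (skew != 0) {
    f <- (exp(skew * z) - 1) / skew
    mf <- (exp(skew^2 / 2) - 1) / skew
    vf <- (exp(2 * skew^2) - exp(skew^2)) / skew^2
    z <- (f - mf) / sqrt(vf)
  }
  sqrt(sigma2) * z
}

#' Survival simulation parameters
#'
#' Event times are exponential with per-patient rate
#' `lambda0 * exp(beta . z)` where `z` are the cohort-standardized phantom
#' texture parameters named in `beta`; censoring is administrative, uniform
#' on `censor` (days). The default baseline hazard `log(2)/248` gives a
#' median progression-free survival of 248 days at `z = 0`.
#'
#' @param n cohort size (>= 2).
#' @param lambda0 baseline hazard per day (> 0).
#' @param beta named numeric vector of log hazard ratios per SD of the
#'   phantom parameters (names among `sigma2`, `skew`, `corr_len`); use
#'   `numeric(0)` or zeros for a null cohort.
#' @param censor length-2 positive increasing censoring bounds in days.
#' @param seed integer seed.
#' @return list of class `survival_sim_params`.
#' @export
survival_sim_params <- function(n = 63L, lambda0 = log(2) / 248,
                                beta = c(sigma2 = 1.2, skew = 0.6),
                                censor = c(30, 1200), seed = 1L) {
  stopifnot(n >= 2L, lambda0 > 0, length(censor) == 2L, all(censor > 0),
            censor[1] < censor[2])
  if (length(beta) && is.null(names(beta))) {
    stop("beta must be a named vector over phantom parameters", call. = FALSE)
  }
  structure(list(n = as.integer(n), lambda0 = lambda0, beta = beta,
                 censor = as.numeric(censor), seed = as.integer(seed)),
            class = "survival_sim_params")
}

#' Simulate right-censored exponential event times under a Cox model
#'
#' @param lp numeric vector of linear predictors (one per subject).
#' @param lambda0 baseline hazard per day.
#' @param censor length-2 uniform censoring bounds (days); `NULL` disables
#'   censoring.
#' @param seed integer seed.
#' @return `data.frame` with `pfs_days`, `event`, `lp`.
#' @export
simulate_survival <- function(lp, lambda0 = log(2) / 248,
                              censor = c(30, 1200), seed = 1L) {
  with_seed(seed, {
    n <- length(lp)
    t_event <- stats::rexp(n, rate = lambda0 * exp(lp))
    if (is.null(censor)) {
      data.frame(pfs_days = pmax(t_event, 1e-8), event = 1L, lp = lp)
    } else {
      c_adm <- stats::runif(n, censor[1], censor[2])
      data.frame(pfs_days = pmax(pmin(t_event, c_adm), 1e-8),
                 event = as.integer(t_event <= c_adm), lp = lp)
    }
  })
}

# per-patient phantom parameter draws around a base setting
sample_phantom_params <- function(base, n, seed) {
  with_seed(seed, {
    data.frame(
      sigma2 = stats::rlnorm(n, meanlog = log(base$sigma2), sdlog = 0.6),
      skew = pmax(pmin(stats::rnorm(n, mean = base$skew, sd = 0.5), 1.2), -1.2),
      corr_len = stats::runif(n, 0.75 * base$corr_len, 1.25 * base$corr_len),
      ax1 = base$semi_axes[1] * stats::runif(n, 0.85, 1.15),
      ax2 = base$semi_axes[2] * stats::runif(n, 0.85, 1.15),
      ax3 = base$semi_axes[3] * stats::runif(n, 0.85, 1.15))
  })
}

#' Generate a synthetic cohort with texture-linked progression times
#'
#' Per patient, phantom parameters are drawn around `base`, an image/mask
#' pair is synthesized, and a progression time is simulated from an
#' exponential proportional-hazards model whose linear predictor is
#' `beta . z` with `z` the cohort-standardized texture parameters. Clinical
#' covariates (sex, age, smoking) are drawn independently unless
#' `beta_clinical` links them to the hazard. The ground-truth table records
#' the drawn parameters, their standardized values and the true linear
#' predictor.
#'
#' @param sparams a [survival_sim_params].
#' @param base a [phantom_params] around which per-patient parameters vary.
#' @param images synthesize image/mask pairs (set FALSE for survival-only
#'   simulations, e.g. calibration studies).
#' @param beta_clinical optional named vector over `age_years`, `smoking`,
#'   `sex` adding clinical effects to the hazard (per SD / per level).
#' @param cohort_label label stored in the clinical table.
#' @return list with `volumes` (named list of img/mask pairs, or NULL),
#'   `clinical` (validated clinical table) and `truth` (ground-truth table).
#' @export
generate_cohort <- function(sparams, base = phantom_params(), images = TRUE,
                            beta_clinical = NULL, cohort_label = "synthetic") {
  stopifnot(inherits(sparams, "survival_sim_params"))
  n <- sparams$n
  seed <- sparams$seed
  pp <- sample_phantom_params(base, n, seed)
  ids <- sprintf("P%03d", seq_len(n))
  beta <- sparams$beta
  beta <- beta[beta != 0]
  zmat <- matrix(0, n, max(1L, length(beta)))
  lp <- rep(0, n)
  zcols <- list()
  for (nm in names(beta)) {
    x <- pp[[nm]]
    if (is.null(x)) stop(sprintf("beta names a missing phantom parameter '%s'", nm),
                         call. = FALSE)
    if (stats::sd(x) < 1e-12) {
      warning(sprintf("degenerate sampler: '%s' is constant but has nonzero effect", nm))
      z <- rep(0, n)
    } else {
      z <- as.numeric(scale(x))
    }
    zcols[[paste0("z_", nm)]] <- z
    lp <- lp + beta[[nm]] * z
  }
  clin <- with_seed(seed + 104729, {
    data.frame(
      patient_id = ids,
      sex = sample(c("male", "female"), n, replace = TRUE),
      age_years = round(pmax(stats::rnorm(n, 55, 12), 20)),
      smoking = sample(c("smoker", "nonsmoker"), n, replace = TRUE,
                       prob = c(0.2, 0.8)),
      stringsAsFactors = FALSE)
  })
  if (!is.null(beta_clinical)) {
    for (nm in names(beta_clinical)) {
      x <- switch(nm,
                  age_years = as.numeric(scale(clin$age_years)),
                  smoking = as.numeric(clin$smoking == "smoker"),
                  sex = as.numeric(clin$sex == "male"),
                  stop(sprintf("unknown clinical covariate '%s'", nm)))
      lp <- lp + beta_clinical[[nm]] * x
    }
  }
  surv <- simulate_survival(lp, sparams$lambda0, sparams$censor,
                            seed = seed + 15485863)
  clin$pfs_days <- surv$pfs_days
  clin$event <- surv$event
  clin$cohort_label <- cohort_label
  clin <- validate_clinical(clin)
  truth <- data.frame(patient_id = ids, pp, stringsAsFactors = FALSE)
  for (nm in names(zcols)) truth[[nm]] <- zcols[[nm]]
  truth$lp <- lp
  volumes <- NULL
  if (images) {
    volumes <- vector("list", n)
    names(volumes) <- ids
    for (i in seq_len(n)) {
      pi <- phantom_params(shape = base$shape, spacing = base$spacing,
                           semi_axes = c(pp$ax1[i], pp$ax2[i], pp$ax3[i]),
                           background = base$background,
                           noise_sd = base$noise_sd, base = base$base,
                           sigma2 = pp$sigma2[i], corr_len = pp$corr_len[i],
                           skew = pp$skew[i])
      volumes[[i]] <- generate_phantom(pi, seed = (seed + 7919 * i) %% 2147483647)
    }
  }
  list(volumes = volumes, clinical = clin, truth = truth)
}

#' @rdname generate_cohort
#' @details `null_cohort()` forces all texture effects to zero: progression
#'   times are independent of the images, emulating a cohort in which the
#'   signature has no true prognostic value.
#' @export
null_cohort <- function(sparams, base = phantom_params(), images = TRUE,
                        cohort_label = "null") {
  sparams$beta <- stats::setNames(numeric(0), character(0))
  generate_cohort(sparams, base = base, images = images,
                  cohort_label = cohort_label)
}

#' Write a generated cohort to a directory
#'
#' Volumes go to `<dir>/images/<id>.nrrd` and `<dir>/masks/<id>.nrrd`;
#' the clinical and ground-truth tables to `clinical.csv` / `truth.csv`.
#'
#' @param cohort result of [generate_cohort].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$volumes)) {
    for (id in names(cohort$volumes)) {
      write_image(cohort$volumes[[id]]$img,
                  file.path(dir, "images", paste0(id, ".nrrd")))
      write_image(cohort$volumes[[id]]$mask,
                  file.path(dir, "masks", paste0(id, ".nrrd")))
    }
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
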