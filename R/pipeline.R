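#' Pipeline configuration
#'
#' A single configuration drives all pipeline stages. `pipeline_config()`
#' accepts a YAML file path or a nested list, fills in documented defaults
#' and validates ranges. Every stage records the resolved configuration hash
#' and seed in its JSON output, so artifacts are traceable to the exact run
#' settings.
#'
#' Sections and defaults:
#' \itemize{
#'   \item paths: `cohort_dir`, `output_dir` (required).
#'   \item simulation: `n_patients` (63), `seed` (1), `lambda0` (log(2)/248),
#'     `beta` (sigma2 = 1.2, skew = 0.6), `censor` (30, 1200), `phantom`
#'     (arguments of [phantom_params]).
#'   \item extraction: `n_levels` (32), `distance` (1), `resample_mm` (1),
#'     `wavelet` (TRUE).
#'   \item selection: `pearson_threshold` (0.8), `folds` (10),
#'     `split_ratio` (0.5), `seed` (1).
#'   \item evaluation: `horizon_days` (183), `n_boot` (2000).
#' }
#'
#' The cohort-size key is deliberately named `n_patients`, not `n`: bare `n`
#' is a boolean token in YAML 1.1 and would silently parse as `FALSE`.
#'
#' @param config YAML file path or nested list.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- list(
    paths = list(cohort_dir = NULL, output_dir = NULL),
    simulation = list(n_patients = 63L, seed = 1L, lambda0 = log(2) / 248,
                      beta = list(sigma2 = 1.2, skew = 0.6),
                      censor = c(30, 1200), phantom = list()),
    extraction = list(n_levels = 32L, distance = 1L, resample_mm = 1,
                      wavelet = TRUE),
    selection = list(pearson_threshold = 0.8, folds = 10L, split_ratio = 0.5,
                     seed = 1L),
    evaluation = list(horizon_days = 183, n_boot = 2000L))
  cfg <- utils::modifyList(def, config)
  if (!is.null(cfg$simulation[["n"]]) || !is.null(cfg$simulation[["FALSE"]])) {
    stop(paste0("unknown simulation key 'n': use 'n_patients' ",
                "(YAML 1.1 parses a bare 'n' key as a boolean)"), call. = FALSE)
  }
  if (is.null(cfg$paths$cohort_dir) || is.null(cfg$paths$output_dir)) {
    stop("config must set paths$cohort_dir and paths$output_dir", call. = FALSE)
  }
  with(cfg$selection, stopifnot(pearson_threshold > 0, pearson_threshold <= 1,
                                folds >= 2L, split_ratio > 0, split_ratio < 1))
  stopifnot(cfg$evaluation$horizon_days > 0, cfg$evaluation$n_boot >= 1)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

plog <- function(cfg, stage, ...) {
  kv <- c(...)
  line <- paste0("stage=", stage,
                 if (length(kv)) paste0(" ", paste0(names(kv), "=", kv,
                                                    collapse = " ")) else "")
  dir.create(cfg$paths$output_dir, recursive = TRUE, showWarnings = FALSE)
  cat(paste0(line, "\n"),
      file = file.path(cfg$paths$output_dir, "pipeline.log"), append = TRUE)
  message(line)
  invisible(line)
}

need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact '%s'; run %s first", path,
                 producer), call. = FALSE)
  }
  path
}

#' Pipeline stages
#'
#' Thin, idempotent drivers tying the package stages together; each consumes
#' the artifacts of the previous stage from disk and writes its own under the
#' configured directories. Identical config + seed gives byte-identical JSON
#' outputs. `pipeline_run_all()` runs simulate, extract, select, fit and
#' evaluate in order.
#'
#' @param cfg a [pipeline_config] (or YAML path / list coerced through it).
#' @return the written artifact path(s), invisibly.
#' @export
pipeline_simulate <- function(cfg) {
  cfg <- as_pipeline_config(cfg)
  sim <- cfg$simulation
  base <- do.call(phantom_params, sim$phantom)
  sp <- survival_sim_params(n = sim$n_patients, lambda0 = sim$lambda0,
                            beta = unlist(sim$beta), censor = sim$censor,
                            seed = sim$seed)
  cohort <- generate_cohort(sp, base = base)
  write_cohort(cohort, cfg$paths$cohort_dir)
  plog(cfg, "simulate", n = sim$n_patients, seed = sim$seed,
       events = sum(cohort$clinical$event))
  invisible(cfg$paths$cohort_dir)
}

#' @rdname pipeline_simulate
#' @export
pipeline_extract <- function(cfg) {
  cfg <- as_pipeline_config(cfg)
  cdir <- cfg$paths$cohort_dir
  clin <- read_clinical(need_artifact(file.path(cdir, "clinical.csv"),
                                      "pipeline_simulate"))
  ecfg <- extraction_config(cfg$extraction$n_levels, cfg$extraction$distance,
                            cfg$extraction$resample_mm, cfg$extraction$wavelet)
  volumes <- lapply(clin$patient_id, function(id) {
    img <- read_image(need_artifact(
      file.path(cdir, "images", paste0(id, ".nrrd")), "pipeline_simulate"))
    list(img = img, mask = read_mask(
      file.path(cdir, "masks", paste0(id, ".nrrd")), img))
  })
  names(volumes) <- clin$patient_id
  feats <- extract_cohort(volumes, ecfg)
  out <- file.path(cfg$paths$output_dir, "features.csv")
  dir.create(cfg$paths$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(feats, out)
  plog(cfg, "extract", n = nrow(feats), features = ncol(feats) - 1L)
  invisible(out)
}

#' @rdname pipeline_simulate
#' @export
pipeline_select <- function(cfg) {
  cfg <- as_pipeline_config(cfg)
  odir <- cfg$paths$output_dir
  feats <- read_feature_table(need_artifact(file.path(odir, "features.csv"),
                                            "pipeline_extract"))
  clin <- read_clinical(file.path(cfg$paths$cohort_dir, "clinical.csv"))
  sel_cfg <- cfg$selection
  split <- split_cohort(clin, ratio = sel_cfg$split_ratio, seed = sel_cfg$seed)
  tr <- feats[feats$patient_id %in% split$train, , drop = FALSE]
  va <- feats[feats$patient_id %in% split$validation, , drop = FALSE]
  norm <- suppressWarnings(zscore_fit_apply(tr, others = list(validation = va)))
  surviving <- pearson_filter(norm$train, threshold = sel_cfg$pearson_threshold)
  tr_clin <- clin[clin$patient_id %in% split$train, ]
  sel <- lasso_cox_cv(norm$train[, c("patient_id", surviving)], tr_clin,
                      folds = sel_cfg$folds, seed = sel_cfg$seed)
  artifact <- list(config_hash = cfg$hash, seed = sel_cfg$seed,
                   split = split, surviving = surviving,
                   lambda_grid = sel$lambda, cv_deviance = sel$cvm,
                   cv_deviance_sd = sel$cvsd, lambda_min = sel$lambda_min,
                   nonzero = as.list(sel$nonzero),
                   normalization = list(mean = as.list(norm$state$mean),
                                        sd = as.list(norm$state$sd)))
  out <- file.path(odir, "selection.json")
  write_json_artifact(artifact, out)
  plog(cfg, "select", surviving = length(surviving),
       nonzero = length(sel$nonzero),
       lambda_min = format(sel$lambda_min, digits = 6))
  invisible(out)
}

#' @rdname pipeline_simulate
#' @export
pipeline_fit <- function(cfg) {
  cfg <- as_pipeline_config(cfg)
  odir <- cfg$paths$output_dir
  sel <- read_json_artifact(need_artifact(file.path(odir, "selection.json"),
                                          "pipeline_select"))
  feats <- read_feature_table(file.path(odir, "features.csv"))
  clin <- read_clinical(file.path(cfg$paths$cohort_dir, "clinical.csv"))
  chosen <- names(sel$nonzero)
  if (length(chosen) == 0L) {
    stop("selection stage kept no feature; cannot fit a signature",
         call. = FALSE)
  }
  state <- list(mean = unlist(sel$normalization$mean),
                sd = unlist(sel$normalization$sd),
                features = names(sel$normalization$mean))
  tr <- zscore_apply(feats[feats$patient_id %in% sel$split$train, ], state)
  tr_clin <- clin[clin$patient_id %in% sel$split$train, ]
  model <- withCallingHandlers(
    fit_signature(tr[, c("patient_id", chosen)], tr_clin),
    warning = function(w) {
      plog(cfg, "fit", warning = shQuote(conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  artifact <- list(config_hash = cfg$hash, seed = cfg$selection$seed,
                   features = model$features,
                   coefficients = as.list(model$coefficients),
                   center = as.list(model$center), cutoff = model$cutoff,
                   epv = model$epv)
  out <- file.path(odir, "signature.json")
  write_json_artifact(artifact, out)
  plog(cfg, "fit", features = length(chosen),
       epv = model$epv, cutoff = format(model$cutoff, digits = 6))
  invisible(out)
}

#' @rdname pipeline_simulate
#' @export
pipeline_evaluate <- function(cfg) {
  cfg <- as_pipeline_config(cfg)
  odir <- cfg$paths$output_dir
  sigj <- read_json_artifact(need_artifact(file.path(odir, "signature.json"),
                                           "pipeline_fit"))
  sel <- read_json_artifact(file.path(odir, "selection.json"))
  feats <- read_feature_table(file.path(odir, "features.csv"))
  clin <- read_clinical(file.path(cfg$paths$cohort_dir, "clinical.csv"))
  state <- list(mean = unlist(sel$normalization$mean),
                sd = unlist(sel$normalization$sd),
                features = names(sel$normalization$mean))
  chosen <- sigj$features
  tr <- zscore_apply(feats[feats$patient_id %in% sel$split$train, ], state)
  va <- zscore_apply(feats[feats$patient_id %in% sel$split$validation, ], state)
  tr_clin <- clin[clin$patient_id %in% sel$split$train, ]
  va_clin <- clin[clin$patient_id %in% sel$split$validation, ]
  model <- fit_signature(tr[, c("patient_id", chosen)], tr_clin)
  ev <- evaluate_signature(model,
                           cohorts = list(
                             train = list(features = tr, clinical = tr_clin),
                             validation = list(features = va,
                                               clinical = va_clin)),
                           horizon = cfg$evaluation$horizon_days,
                           n_boot = cfg$evaluation$n_boot,
                           seed = cfg$selection$seed)
  cc <- clinical_and_combined_models(tr_clin, va_clin,
                                     predict(model, tr), predict(model, va))
  report <- list(config_hash = cfg$hash, seed = cfg$selection$seed,
                 horizon_days = cfg$evaluation$horizon_days,
                 cohorts = lapply(ev, function(r) list(
                   n = r$n, events = r$events,
                   cindex = r$cindex[c("cindex", "lower", "upper")],
                   auc = r$auc$auc, logrank_p = r$logrank$p,
                   median_pfs = as.list(r$median_pfs))),
                 model_cindex = cc$cindex, clinical_selected = cc$selected,
                 clinical_note = cc$note)
  out <- file.path(odir, "evaluation.json")
  write_json_artifact(report, out)
  # per-curve CSVs for plotting
  for (nm in names(ev)) {
    km <- do.call(rbind, lapply(names(ev[[nm]]$km), function(g) {
      k <- ev[[nm]]$km[[g]]
      data.frame(group = g, time = k$time, surv = k$surv, n_risk = k$n_risk)
    }))
    utils::write.csv(km, file.path(odir, sprintf("km_%s.csv", nm)),
                     row.names = FALSE)
    if (!is.null(ev[[nm]]$auc$roc)) {
      utils::write.csv(ev[[nm]]$auc$roc,
                       file.path(odir, sprintf("roc_%s.csv", nm)),
                       row.names = FALSE)
    }
  }
  forest <- hazard_ratio_table(
    data.frame(signature = as.numeric(scale(predict(model, va))),
               age_years = va_clin$age_years,
               smoking = as.numeric(va_clin$smoking == "smoker"),
               sex = as.numeric(va_clin$sex == "male")),
    va_clin$pfs_days, va_clin$event)
  utils::write.csv(forest, file.path(odir, "forest_validation.csv"),
                   row.names = FALSE)
  plog(cfg, "evaluate",
       cindex_validation = format(ev$validation$cindex$cindex, digits = 4),
       logrank_p = format(ev$validation$logrank$p, digits = 4))
  invisible(out)
}

#' @rdname pipeline_simulate
#' @export
pipeline_run_all <- function(cfg) {
  cfg <- as_pipeline_config(cfg)
  pipeline_simulate(cfg)
  pipeline_extract(cfg)
  pipeline_select(cfg)
  pipeline_fit(cfg)
  out <- pipeline_evaluate(cfg)
  plog(cfg, "run_all", status = "done")
  invisible(out)
}

as_pipeline_config <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) cfg else pipeline_config(cfg)
}
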