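#' Train-cohort z-score normalization
#'
#' Fits per-feature mean and standard deviation (sample, divisor n-1) on the
#' training table only, then applies the same transform to the training table
#' and to any other cohorts — validation data never influence the state.
#' Zero-variance training features are dropped with a warning.
#'
#' @param train feature `data.frame` (`patient_id` + numeric columns).
#' @param others optional named list of further feature `data.frame`s to
#'   transform with the training state.
#' @return list with `train`, `others`, and `state` (means, sds, kept names).
#' @export
zscore_fit_apply <- function(train, others = list()) {
  feats <- setdiff(names(train), "patient_id")
  x <- as.matrix(train[, feats, drop = FALSE])
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  kept <- feats[sd_ > 1e-12]
  dropped <- setdiff(feats, kept)
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  state <- list(mean = mu[kept], sd = sd_[kept], features = kept)
  list(train = zscore_apply(train, state),
       others = lapply(others, zscore_apply, state = state),
       state = state)
}

#' @rdname zscore_fit_apply
#' @param table a feature `data.frame` to transform.
#' @param state a normalization state from `zscore_fit_apply()$state`.
#' @export
zscore_apply <- function(table, state) {
  x <- as.matrix(table[, state$features, drop = FALSE])
  x <- sweep(sweep(x, 2, state$mean, `-`), 2, state$sd, `/`)
  cbind(table[, "patient_id", drop = FALSE], as.data.frame(x))
}

#' Pearson redundancy pruning
#'
#' Iteratively removes features until no surviving pair has an absolute
#' Pearson correlation above `threshold`. Removal is deterministic: at each
#' step the feature with the most |r| > threshold partners is dropped; ties
#' go to the feature with the larger mean |r| against the other survivors,
#' then to the later position in registry (column) order. Constant columns
#' are removed first.
#'
#' @param table feature `data.frame` (`patient_id` + numeric columns).
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return character vector of surviving feature names, in column order.
#' @export
pearson_filter <- function(table, threshold = 0.8) {
  feats <- setdiff(names(table), "patient_id")
  if (length(feats) < 2L) return(feats)
  x <- as.matrix(table[, feats, drop = FALSE])
  const <- apply(x, 2, stats::sd) <= 1e-12
  keep <- feats[!const]
  if (length(keep) < 2L) return(keep)
  r <- abs(stats::cor(x[, keep, drop = FALSE]))
  diag(r) <- 0
  repeat {
    high <- r > threshold
    deg <- rowSums(high)
    if (max(deg) == 0) break
    cand <- which(deg == max(deg))
    if (length(cand) > 1L) {
      mr <- rowMeans(r[cand, , drop = FALSE])
      cand <- cand[mr == max(mr)]
    }
    drop_idx <- max(cand)  # later registry position loses
    r <- r[-drop_idx, -drop_idx, drop = FALSE]
    keep <- keep[-drop_idx]
    if (length(keep) < 2L) break
  }
  keep
}

#' LASSO-penalized Cox selection with cross-validated lambda
#'
#' L1-penalized Cox partial-likelihood regression over a log-spaced lambda
#' grid (100 values down to 0.01 of the data-derived maximum), with the
#' penalty weight chosen to minimize the mean cross-validated partial
#' likelihood deviance over `folds` folds stratified by event status.
#' Features are assumed already normalized (no internal standardization).
#' Ties use the Breslow approximation (glmnet's convention).
#'
#' @param table feature `data.frame` (`patient_id` + normalized columns).
#' @param clinical table with `pfs_days` and `event`, aligned with `table`
#'   rows by `patient_id`.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed driving the fold assignment.
#' @return list of class `selection_result`: `lambda` (grid), `path`
#'   (coefficients per grid point), `cvm`/`cvsd` (CV deviance curve),
#'   `lambda_min`, `nonzero` (named coefficients at `lambda_min`),
#'   `features` (candidate set).
#' @export
lasso_cox_cv <- function(table, clinical, folds = 10L, seed = 1L) {
  feats <- setdiff(names(table), "patient_id")
  stopifnot(length(feats) >= 1L, folds >= 2L)
  ord <- match(table$patient_id, clinical$patient_id)
  if (any(is.na(ord))) stop("feature/clinical patient_id mismatch", call. = FALSE)
  cl <- clinical[ord, ]
  if (sum(cl$event) < folds) {
    stop("need at least one observed event per CV fold", call. = FALSE)
  }
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- survival::Surv(cl$pfs_days, cl$event)
  foldid <- with_seed(seed, stratified_folds(cl$event, folds))
  fit <- glmnet::glmnet(x, y, family = "cox", nlambda = 100,
                        lambda.min.ratio = 0.01, standardize = FALSE)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", lambda = fit$lambda,
                          foldid = foldid, standardize = FALSE,
                          type.measure = "deviance")
  lam <- cv$lambda.min
  beta <- as.matrix(glmnet::coef.glmnet(cv$glmnet.fit, s = lam))[, 1]
  nz <- beta[beta != 0]
  structure(list(lambda = cv$lambda, path = as.matrix(cv$glmnet.fit$beta),
                 cvm = cv$cvm, cvsd = cv$cvsd, lambda_min = lam,
                 nonzero = nz, features = feats, foldid = foldid),
            class = "selection_result")
}

stratified_folds <- function(event, folds) {
  foldid <- integer(length(event))
  for (g in unique(event)) {
    idx <- sample(which(event == g))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  foldid
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d candidates, lambda_min = %.4g, %d nonzero\n",
              length(x$features), x$lambda_min, length(x$nonzero)))
  if (length(x$nonzero)) {
    print(round(x$nonzero, 4))
  }
  invisible(x)
}

#' Events-per-variable check (1-in-10 rule)
#'
#' Warns when the number of model features reaches or exceeds one tenth of
#' the observed events, the classical events-per-variable guideline for Cox
#' models. The check warns rather than blocks: small discovery cohorts
#' routinely run close to or past the limit.
#'
#' @param n_selected number of features entering the multivariate Cox fit.
#' @param n_events number of observed events.
#' @return "pass" or "warn" (invisibly, with an R warning in the latter case).
#' @export
epv_check <- function(n_selected, n_events) {
  stopifnot(n_selected >= 0, n_events >= 0)
  if (n_events == 0 || n_selected >= n_events / 10) {
    warning(sprintf(
      "events-per-variable check: %d feature(s) against %d event(s) (limit < %.1f)",
      n_selected, n_events, n_events / 10))
    return(invisible("warn"))
  }
  invisible("pass")
}

#' Stratified random cohort split
#'
#' @param clinical validated clinical table.
#' @param ratio training fraction (default 0.5 for a 1:1 split).
#' @param seed integer seed.
#' @return list with `train` and `validation` patient_id vectors; the split
#'   is stratified by event status.
#' @export
split_cohort <- function(clinical, ratio = 0.5, seed = 1L) {
  with_seed(seed, {
    train <- character(0)
    for (g in unique(clinical$event)) {
      ids <- clinical$patient_id[clinical$event == g]
      k <- round(length(ids) * ratio)
      train <- c(train, sample(ids, k))
    }
    list(train = sort(train),
         validation = sort(setdiff(clinical$patient_id, train)))
  })
}

#' Selection stability over repeated random cohort allocations
#'
#' Repeats the discovery chain (normalization, Pearson pruning, CV-LASSO-Cox)
#' on the training half of `n_splits` random event-stratified 1:1 cohort
#' allocations and reports how often each feature ends up with a nonzero
#' coefficient.
#'
#' @param features feature `data.frame` for the full cohort.
#' @param clinical matching clinical table.
#' @param n_splits number of random allocations (default 10).
#' @param ratio training fraction per split (default 0.5).
#' @param threshold Pearson pruning threshold.
#' @param folds CV folds.
#' @param seed integer seed.
#' @return list with `frequency` (named selection frequency in [0, 1]) and
#'   `selected` (list of per-split nonzero feature sets).
#' @export
stability_analysis <- function(features, clinical, n_splits = 10L,
                               ratio = 0.5, threshold = 0.8, folds = 10L,
                               seed = 1L) {
  stopifnot(nrow(clinical) >= 4L)
  feats <- setdiff(names(features), "patient_id")
  hits <- stats::setNames(numeric(length(feats)), feats)
  selected <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- split_cohort(clinical, ratio = ratio, seed = seed + 31L * s)
    tr_feat <- features[features$patient_id %in% sp$train, , drop = FALSE]
    tr_clin <- clinical[clinical$patient_id %in% sp$train, , drop = FALSE]
    norm <- suppressWarnings(zscore_fit_apply(tr_feat))
    surv_names <- pearson_filter(norm$train, threshold = threshold)
    sel <- lasso_cox_cv(norm$train[, c("patient_id", surv_names), drop = FALSE],
                        tr_clin, folds = folds, seed = seed + 101L * s)
    nm <- names(sel$nonzero)
    selected[[s]] <- nm
    hits[nm] <- hits[nm] + 1
  }
  list(frequency = hits / n_splits, selected = selected)
}
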