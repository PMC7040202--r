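#' Fit a Cox radiomic signature
#'
#' Fits an unpenalized multivariate Cox proportional hazards model (Breslow
#' ties) on the selected, normalized features. The signature score of a
#' patient is the Cox linear predictor (centered on the training means);
#' higher score = higher hazard of progression. The dichotomization cutoff is
#' the median of the training scores and is fixed at fit time — validation
#' cohorts are always stratified with the training cutoff.
#'
#' @param features normalized feature `data.frame` (`patient_id` + the
#'   selected columns only).
#' @param clinical matching clinical table (needs `pfs_days`, `event`).
#' @return object of class `radiomic_signature` with `coefficients`,
#'   `cutoff`, `features`, `fit` (the underlying `coxph` fit) and
#'   `train_scores`.
#' @seealso [predict.radiomic_signature], [stratify], [evaluate_signature]
#' @export
fit_signature <- function(features, clinical) {
  feats <- setdiff(names(features), "patient_id")
  stopifnot(length(feats) >= 1L)
  ord <- match(features$patient_id, clinical$patient_id)
  if (any(is.na(ord))) stop("feature/clinical patient_id mismatch", call. = FALSE)
  cl <- clinical[ord, ]
  if (sum(cl$event) < 1L) stop("no observed events; cannot fit", call. = FALSE)
  x <- as.matrix(features[, feats, drop = FALSE])
  const <- apply(x, 2, stats::sd) <= 1e-12
  if (any(const)) {
    stop(sprintf("constant feature(s) rejected: %s",
                 paste(feats[const], collapse = ", ")), call. = FALSE)
  }
  epv_status <- withCallingHandlers(
    epv_check(length(feats), sum(cl$event)),
    warning = function(w) invokeRestart("muffleWarning"))
  df <- data.frame(time = cl$pfs_days, status = cl$event, x,
                   check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(sprintf("`%s`", feats), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  if (!is.null(fit$info) && isTRUE(fit$info$flag)) {
    warning("monotone likelihood flagged in Cox fit")
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox fit did not converge (NA coefficients); see summary(fit)",
         call. = FALSE)
  }
  scores <- as.numeric(stats::predict(fit, type = "lp"))
  obj <- structure(list(
    coefficients = stats::coef(fit),
    features = feats,
    cutoff = stats::median(scores),
    center = colMeans(x),
    fit = fit,
    epv = epv_status,
    train_scores = stats::setNames(scores, features$patient_id)),
    class = "radiomic_signature")
  obj
}

#' @export
print.radiomic_signature <- function(x, ...) {
  cat("Cox radiomic signature\n")
  cat(sprintf("  score = %s\n",
              paste(sprintf("%+.4g*%s", x$coefficients, x$features),
                    collapse = " ")))
  cat(sprintf("  training-median cutoff: %.4g (score > cutoff => high risk)\n",
              x$cutoff))
  invisible(x)
}

#' @export
coef.radiomic_signature <- function(object, ...) object$coefficients

#' @export
summary.radiomic_signature <- function(object, ...) {
  s <- summary(object$fit)
  cat("Cox radiomic signature (", length(object$features), " features, ",
      s$nevent, " events)\n", sep = "")
  print(s$coefficients)
  cat(sprintf("cutoff (training median score): %.4g\n", object$cutoff))
  invisible(s)
}

#' Score new patients with a fitted signature
#'
#' @param object a `radiomic_signature`.
#' @param newdata feature `data.frame` holding the signature's feature
#'   columns on the training normalization scale.
#' @param ... unused.
#' @return named numeric vector of signature scores (Cox linear predictors).
#' @export
predict.radiomic_signature <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    stop(sprintf("newdata lacks signature feature(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  lp <- as.numeric(sweep(x, 2, object$center, `-`) %*% object$coefficients)
  if ("patient_id" %in% names(newdata)) names(lp) <- newdata$patient_id
  lp
}

#' Dichotomize signature scores at the training-median cutoff
#'
#' Scores strictly above the cutoff become `"high"` (rapid progression
#' expected); ties and lower scores go to `"low"`.
#'
#' @param model a fitted `radiomic_signature` (source of the cutoff).
#' @param scores numeric scores to stratify (defaults to training scores).
#' @return factor with levels `low`, `high`.
#' @export
stratify <- function(model, scores = model$train_scores) {
  stopifnot(inherits(model, "radiomic_signature"))
  factor(ifelse(scores > model$cutoff, "high", "low"),
         levels = c("low", "high"))
}

#' The published radiomic-signature scoring rule
#'
#' A fixed linear scoring rule with frozen published coefficients:
#' \deqn{0.312 \times (\mathrm{first\ order\ minimum} \times \mathrm{cluster\ shade})
#'   + 0.602 \times \mathrm{SRHGLE}.}
#' Inputs are expected on the original study's normalized feature scale; the
#' rule is provided as a frozen reference scorer, not refitted.
#'
#' @param min_times_clustershade product of the first-order minimum and the
#'   GLCM cluster shade.
#' @param srhgle the GLRLM short run high gray-level emphasis.
#' @return numeric signature score.
#' @examples
#' published_signature(1, 0)  # 0.312
#' published_signature(0, 1)  # 0.602
#' @export
published_signature <- function(min_times_clustershade, srhgle) {
  stopifnot(is.finite(min_times_clustershade), is.finite(srhgle))
  0.312 * min_times_clustershade + 0.602 * srhgle
}
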