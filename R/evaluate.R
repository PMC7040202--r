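#' Kaplan-Meier curve and median survival
#'
#' Product-limit estimator of the survival function, with the median defined
#' as the earliest observed time at which the estimate drops to 0.5 or below
#' (`NA` with `median_reached = FALSE` if the curve never does).
#'
#' @param time event/censoring times in days.
#' @param event 1 = event observed, 0 = censored.
#' @return list with `time`, `surv`, `n_risk`, `n_event`, `median`,
#'   `median_reached`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  reached <- any(fit$surv <= 0.5)
  med <- if (reached) min(fit$time[fit$surv <= 0.5]) else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med, median_reached = reached)
}

#' Weighted (G-rho) log-rank test
#'
#' Harrington-Fleming G-rho family with weights \eqn{\hat S(t-)^\rho}:
#' `rho = 0` is the standard log-rank test, `rho = 1` the Peto-Peto
#' modification emphasizing early differences. Exactly two groups; p-value
#' from the chi-square distribution with 1 df.
#'
#' @param groups two-level grouping factor/vector.
#' @param time,event survival outcome.
#' @param rho weighting exponent (default 1).
#' @return list with `chisq`, `p`, `rho`, `n` per group.
#' @export
grho_logrank <- function(groups, time, event, rho = 1) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2L) {
    stop("G-rho log-rank needs exactly two non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups, rho = rho)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p = unname(p), rho = rho, n = sd$n)
}

#' Harrell's concordance index with bootstrap confidence interval
#'
#' Fraction of usable patient pairs in which the higher-scoring patient
#' progresses first. A pair (i, j) is usable when the earlier time is an
#' observed event and the times differ; tied scores count 0.5. The optional
#' 95% CI is a seeded percentile bootstrap over patients.
#'
#' @param scores risk scores (higher = higher hazard).
#' @param time,event survival outcome.
#' @param ci compute a bootstrap CI (default TRUE).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return list with `cindex`, `n_pairs`, and (with `ci`) `lower`, `upper`.
#' @export
harrell_cindex <- function(scores, time, event, ci = TRUE, n_boot = 2000L,
                           seed = 1L) {
  est <- cindex_point(scores, time, event)
  if (is.na(est$cindex)) stop("no comparable pairs", call. = FALSE)
  out <- list(cindex = est$cindex, n_pairs = est$n_pairs)
  if (ci) {
    n <- length(scores)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        cindex_point(scores[idx], time[idx], event[idx])$cindex
      }, 0)
    })
    qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out$lower <- qs[1]; out$upper <- qs[2]
  }
  out
}

cindex_point <- function(scores, time, event) {
  # usable pairs: t_i < t_j with event_i = 1
  comp <- outer(time, time, `<`) & (event == 1)
  n_pairs <- sum(comp)
  if (n_pairs == 0L) return(list(cindex = NA_real_, n_pairs = 0L))
  sdiff <- outer(scores, scores, `-`)
  conc <- sum(sdiff[comp] > 0) + 0.5 * sum(sdiff[comp] == 0)
  list(cindex = conc / n_pairs, n_pairs = n_pairs)
}

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' Discrimination at a fixed horizon t: cases are patients with an observed
#' event by t, controls are patients event-free past t. Inverse probability
#' of censoring weights come from the Kaplan-Meier estimate of the censoring
#' distribution (cases weighted by 1/G(T-), controls by 1/G(t)). Without
#' censoring this reduces to the empirical (rank-sum) AUC of the binary
#' classification "event by t".
#'
#' @param scores risk scores (higher = higher hazard).
#' @param time,event survival outcome.
#' @param horizon evaluation time in days (default 183, i.e. 6 months).
#' @return list with `auc`, `horizon`, `n_cases`, `n_controls`.
#' @export
td_auc <- function(scores, time, event, horizon = 183) {
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (length(cases) == 0L || length(controls) == 0L) {
    stop(sprintf("no cases or no controls at horizon %g days", horizon),
         call. = FALSE)
  }
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  g_case <- vapply(time[cases], function(t) G(t - 1e-9), 0)
  g_ctrl <- G(horizon)
  w_case <- 1 / pmax(g_case, 1e-12)
  w_ctrl <- rep(1 / pmax(g_ctrl, 1e-12), length(controls))
  sc <- scores[cases]; sk <- scores[controls]
  gt <- outer(sc, sk, `>`); eq <- outer(sc, sk, `==`)
  wmat <- outer(w_case, w_ctrl)
  auc <- sum(wmat * (gt + 0.5 * eq)) / sum(wmat)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(cc) sum(w_case[sc >= cc]) / sum(w_case), 0)),
    fpr = c(0, vapply(thr, function(cc) sum(w_ctrl[sk >= cc]) / sum(w_ctrl), 0)))
  list(auc = auc, horizon = horizon, n_cases = length(cases),
       n_controls = length(controls), roc = roc)
}

#' Univariate hazard-ratio table for a set of prognostic factors
#'
#' One univariate Cox model (Breslow ties) per factor; hazard ratios are per
#' unit for continuous factors and versus the reference level for two-level
#' categorical factors. P-values come from the likelihood-ratio test against
#' the null model. Factors whose fit fails are flagged, not fatal.
#'
#' @param factors `data.frame` of candidate factors (numeric, or
#'   factor/character with two levels).
#' @param time,event survival outcome.
#' @return `data.frame` with `factor`, `hr`, `lower`, `upper`, `p_lrt`,
#'   `note` — ready for a forest plot.
#' @export
hazard_ratio_table <- function(factors, time, event) {
  stopifnot(is.data.frame(factors))
  rows <- lapply(names(factors), function(nm) {
    x <- factors[[nm]]
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      if (nlevels(x) != 2L) {
        return(data.frame(factor = nm, hr = NA, lower = NA, upper = NA,
                          p_lrt = NA, note = "needs exactly 2 levels"))
      }
      x <- as.numeric(x) - 1
    }
    tryCatch({
      fit <- survival::coxph(survival::Surv(time, event) ~ x,
                             ties = "breslow")
      lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
      ciw <- stats::qnorm(0.975) * sqrt(fit$var[1, 1])
      data.frame(factor = nm, hr = exp(fit$coefficients[1]),
                 lower = exp(fit$coefficients[1] - ciw),
                 upper = exp(fit$coefficients[1] + ciw),
                 p_lrt = stats::pchisq(lrt, 1, lower.tail = FALSE),
                 note = "")
    }, error = function(e) {
      data.frame(factor = nm, hr = NA, lower = NA, upper = NA, p_lrt = NA,
                 note = conditionMessage(e))
    }, warning = function(w) {
      suppressWarnings({
        fit <- survival::coxph(survival::Surv(time, event) ~ x,
                               ties = "breslow")
        lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
        ciw <- stats::qnorm(0.975) * sqrt(fit$var[1, 1])
        data.frame(factor = nm, hr = exp(fit$coefficients[1]),
                   lower = exp(fit$coefficients[1] - ciw),
                   upper = exp(fit$coefficients[1] + ciw),
                   p_lrt = stats::pchisq(lrt, 1, lower.tail = FALSE),
                   note = conditionMessage(w))
      })
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clinical and combined (clinical + signature) Cox models
#'
#' Screens the clinical covariates (age, smoking status, sex) univariately on
#' the training cohort (likelihood-ratio p < 0.05), fits a multivariate Cox
#' clinical model on the significant ones, and a combined model adding the
#' radiomic signature score. Reports Harrell C-indices on training and
#' validation cohorts. With no significant covariate the clinical model
#' degenerates to empty (a logged note) and the combined model falls back to
#' the signature alone.
#'
#' @param train_clinical,valid_clinical validated clinical tables.
#' @param train_scores,valid_scores signature scores aligned with the tables.
#' @param alpha univariate screening level (default 0.05).
#' @return list with `screen` (HR table), `selected`, `clinical_model`,
#'   `combined_model`, `cindex` (per model and cohort) and `note`.
#' @export
clinical_and_combined_models <- function(train_clinical, valid_clinical,
                                         train_scores, valid_scores,
                                         alpha = 0.05) {
  covars <- function(cl) data.frame(
    age_years = cl$age_years,
    smoking = as.numeric(cl$smoking == "smoker"),
    sex = as.numeric(cl$sex == "male"))
  xt <- covars(train_clinical); xv <- covars(valid_clinical)
  screen <- hazard_ratio_table(xt, train_clinical$pfs_days,
                               train_clinical$event)
  selected <- screen$factor[!is.na(screen$p_lrt) & screen$p_lrt < alpha]
  note <- ""
  cfun <- function(s, cl) cindex_point(s, cl$pfs_days, cl$event)$cindex
  res <- list(screen = screen, selected = selected)
  if (length(selected) == 0L) {
    note <- "no clinical covariate significant at the screening level"
    res$clinical_model <- NULL
    clin_tr <- NULL
  } else {
    dtr <- data.frame(time = train_clinical$pfs_days,
                      status = train_clinical$event,
                      xt[, selected, drop = FALSE])
    fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                   paste(selected, collapse = " + ")))
    res$clinical_model <- survival::coxph(fml, data = dtr, ties = "breslow")
    clin_tr <- as.numeric(stats::predict(res$clinical_model, type = "lp"))
    clin_va <- as.numeric(stats::predict(
      res$clinical_model,
      newdata = data.frame(xv[, selected, drop = FALSE]), type = "lp"))
  }
  # combined: selected covariates + signature score
  dtr2 <- data.frame(time = train_clinical$pfs_days,
                     status = train_clinical$event, signature = train_scores,
                     xt[, selected, drop = FALSE])
  fml2 <- stats::as.formula(paste("survival::Surv(time, status) ~ signature",
                                  if (length(selected))
                                    paste("+", paste(selected, collapse = " + "))
                                  else ""))
  res$combined_model <- survival::coxph(fml2, data = dtr2, ties = "breslow")
  comb_tr <- as.numeric(stats::predict(res$combined_model, type = "lp"))
  comb_va <- as.numeric(stats::predict(
    res$combined_model,
    newdata = data.frame(signature = valid_scores,
                         xv[, selected, drop = FALSE]), type = "lp"))
  res$cindex <- list(
    signature = c(train = cfun(train_scores, train_clinical),
                  validation = cfun(valid_scores, valid_clinical)),
    clinical = if (length(selected))
      c(train = cfun(clin_tr, train_clinical),
        validation = cfun(clin_va, valid_clinical)) else c(train = NA, validation = NA),
    combined = c(train = cfun(comb_tr, train_clinical),
                 validation = cfun(comb_va, valid_clinical)))
  res$note <- note
  res
}

#' Chi-square comparison of baseline characteristics between two cohorts
#'
#' Pearson chi-square test (no continuity correction, so the statistic equals
#' the textbook formula on the contingency table) per categorical
#' characteristic against the cohort label. Characteristics with an expected
#' cell count of zero are flagged.
#'
#' @param clinical validated clinical table with a 2-level `cohort_label`.
#' @param characteristics columns to test (default sex and smoking status).
#' @return `data.frame` with `characteristic`, `statistic`, `p`, `flag`.
#' @export
compare_baseline <- function(clinical,
                             characteristics = c("sex", "smoking")) {
  lab <- factor(clinical$cohort_label)
  if (nlevels(droplevels(lab)) != 2L) {
    stop("compare_baseline needs exactly two cohorts", call. = FALSE)
  }
  rows <- lapply(characteristics, function(ch) {
    tab <- table(lab, factor(clinical[[ch]]))
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    flag <- if (any(expct == 0)) "zero expected cell" else ""
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(characteristic = ch, statistic = unname(ct$statistic),
               p = unname(ct$p.value), flag = flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a radiomic signature on one or more cohorts
#'
#' For each cohort: signature scores, median-split risk groups (training
#' cutoff), Kaplan-Meier curves with per-group median PFS, G-rho (rho = 1)
#' log-rank p, Harrell C-index with bootstrap CI, and the time-dependent AUC
#' at the horizon. Also reports the per-SD hazard ratio of the score.
#'
#' @param model a fitted [radiomic_signature][fit_signature].
#' @param cohorts named list; each element is a list with `features`
#'   (normalized feature table) and `clinical` (validated clinical table).
#' @param horizon AUC evaluation time in days (default 183 = 6 months).
#' @param n_boot bootstrap replicates for the C-index CI.
#' @param seed integer seed.
#' @return object of class `signature_evaluation` (a named list of per-cohort
#'   reports).
#' @export
evaluate_signature <- function(model, cohorts, horizon = 183,
                               n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(model, "radiomic_signature"), length(cohorts) >= 1L)
  out <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    cl <- co$clinical[match(co$features$patient_id, co$clinical$patient_id), ]
    scores <- predict(model, co$features)
    grp <- stratify(model, scores)
    km <- lapply(split(seq_along(grp), grp), function(ix) {
      km_estimate(cl$pfs_days[ix], cl$event[ix])
    })
    lr <- if (nlevels(droplevels(grp)) == 2L) {
      grho_logrank(grp, cl$pfs_days, cl$event, rho = 1)
    } else list(chisq = NA, p = NA, rho = 1, n = table(grp))
    ci <- harrell_cindex(scores, cl$pfs_days, cl$event, n_boot = n_boot,
                         seed = seed)
    auc <- tryCatch(td_auc(scores, cl$pfs_days, cl$event, horizon),
                    error = function(e) list(auc = NA, horizon = horizon))
    hr <- hazard_ratio_table(
      data.frame(signature_per_sd = as.numeric(scale(scores))),
      cl$pfs_days, cl$event)
    list(cohort = nm, n = nrow(cl), events = sum(cl$event), scores = scores,
         groups = grp, km = km,
         median_pfs = vapply(km, function(k) k$median, 0),
         logrank = lr, cindex = ci, auc = auc, hr = hr)
  })
  names(out) <- names(cohorts)
  structure(out, class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("cohort %s: n=%d events=%d C-index=%.3f (%.3f-%.3f) AUC(%gd)=%.3f logrank p=%.3g\n",
                nm, r$n, r$events, r$cindex$cindex,
                r$cindex$lower %||% NA, r$cindex$upper %||% NA,
                r$auc$horizon, r$auc$auc, r$logrank$p))
    med <- r$median_pfs
    cat(sprintf("  median PFS low/high: %s / %s days\n",
                format(med["low"]), format(med["high"])))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
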