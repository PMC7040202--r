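test_that("published signature rule reproduces its printed coefficients", {
  expect_identical(published_signature(1, 0), 0.312)
  expect_identical(published_signature(0, 1), 0.602)
  expect_equal(published_signature(2, -1), 0.312 * 2 - 0.602)
  expect_equal(published_signature(0, 0), 0)
  expect_error(published_signature(NA, 1))
  expect_error(published_signature(Inf, 1))
})

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  # times 1,2,3,4 all events: S = 3/4, 1/2, 1/4, 0
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  expect_true(km$median_reached)

  # censoring removes from risk without an event step
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  # curve never reaching 0.5
  km3 <- km_estimate(c(5, 6, 7, 8), c(1, 0, 0, 0))
  expect_false(km3$median_reached)
  expect_true(is.na(km3$median))
})

test_that("G-rho log-rank at rho=0 equals the textbook statistic", {
  set.seed(47)
  for (r in 1:5) {
    n <- 60
    grp <- rep(c("a", "b"), each = n / 2)
    time <- rexp(n, rate = ifelse(grp == "a", 1, 1.6))
    event <- as.integer(runif(n) > 0.25)
    if (length(unique(time)) < n) next
    got <- grho_logrank(grp, time, event, rho = 0)
    expect_equal(got$chisq, oracle_logrank(grp, time, event), tolerance = 1e-8)
    expect_equal(got$p, pchisq(got$chisq, 1, lower.tail = FALSE))
  }
})

test_that("rho=1 weighting differs from rho=0 and needs two groups", {
  set.seed(49)
  n <- 80
  grp <- rep(c("a", "b"), each = 40)
  time <- rexp(n, ifelse(grp == "a", 1, 2))
  event <- rep(1L, n)
  g0 <- grho_logrank(grp, time, event, rho = 0)
  g1 <- grho_logrank(grp, time, event, rho = 1)
  expect_equal(g1$rho, 1)
  expect_false(isTRUE(all.equal(g0$chisq, g1$chisq)))
  expect_error(grho_logrank(rep("a", n), time, event), "two")
  expect_error(grho_logrank(rep(c("a", "b", "c"), length.out = n), time, event),
               "two")
})

test_that("C-index matches the 4-patient hand fixture and the naive oracle", {
  # times 1<2<3<4 all events; scores 4,3,1,2: 5 of 6 pairs concordant
  ci <- harrell_cindex(c(4, 3, 1, 2), 1:4, rep(1, 4), ci = FALSE)
  expect_equal(ci$cindex, 5 / 6)
  expect_equal(ci$n_pairs, 6L)

  set.seed(51)
  n <- 60
  sc <- rnorm(n)
  tm <- rexp(n, exp(0.5 * sc))
  ev <- as.integer(runif(n) > 0.3)
  got <- harrell_cindex(sc, tm, ev, ci = FALSE)
  expect_equal(got$cindex, oracle_cindex(sc, tm, ev), tolerance = 1e-12)
})

test_that("C-index is invariant under monotone score transforms, ties = 0.5", {
  set.seed(53)
  n <- 50
  sc <- rnorm(n)
  tm <- rexp(n, exp(sc))
  ev <- rep(1L, n)
  a <- harrell_cindex(sc, tm, ev, ci = FALSE)$cindex
  b <- harrell_cindex(exp(sc), tm, ev, ci = FALSE)$cindex
  expect_equal(a, b, tolerance = 1e-12)
  # all-tied scores give exactly 0.5
  expect_equal(harrell_cindex(rep(1, n), tm, ev, ci = FALSE)$cindex, 0.5)
})

test_that("bootstrap CI brackets the point estimate and is seeded", {
  set.seed(55)
  n <- 80
  sc <- rnorm(n)
  tm <- rexp(n, exp(0.8 * sc))
  ev <- as.integer(runif(n) > 0.2)
  a <- harrell_cindex(sc, tm, ev, n_boot = 200, seed = 7)
  b <- harrell_cindex(sc, tm, ev, n_boot = 200, seed = 7)
  expect_identical(a, b)
  expect_lte(a$lower, a$cindex)
  expect_gte(a$upper, a$cindex)
  expect_gt(a$lower, 0.5)   # strong signal: CI excludes chance
})

test_that("time-dependent AUC equals the rank-sum AUC without censoring", {
  set.seed(57)
  n <- 120
  sc <- rnorm(n)
  tm <- rexp(n, exp(sc))
  ev <- rep(1L, n)
  horizon <- median(tm)
  got <- td_auc(sc, tm, ev, horizon = horizon)
  case <- tm <= horizon
  # naive rank-sum AUC of scores for 'event by horizon'
  num <- 0; den <- 0
  for (i in which(case)) for (j in which(!case)) {
    den <- den + 1
    num <- num + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  }
  expect_equal(got$auc, num / den, tolerance = 1e-12)
  expect_equal(got$n_cases, sum(case))
  # ROC curve is monotone from (0,0) to (1,1)
  expect_equal(got$roc$tpr[1], 0)
  expect_equal(got$roc$tpr[nrow(got$roc)], 1)
  expect_true(all(diff(got$roc$fpr) >= 0))
})

test_that("perfectly separating scores give AUC 1; degenerate cases error", {
  tm <- c(10, 20, 30, 200, 300, 400)
  ev <- rep(1L, 6)
  sc <- c(6, 5, 4, 1, 2, 3)
  expect_equal(td_auc(sc, tm, ev, horizon = 100)$auc, 1)
  expect_error(td_auc(sc, tm, ev, horizon = 1000), "no cases or no controls")
})

test_that("hazard ratio table recovers a known effect with LRT p-values", {
  set.seed(59)
  n <- 250
  x <- rnorm(n)
  surv <- simulate_survival(0.7 * x, seed = 61)
  tab <- hazard_ratio_table(data.frame(risk = x, noise = rnorm(n)),
                            surv$pfs_days, surv$event)
  expect_equal(tab$factor, c("risk", "noise"))
  r <- tab[tab$factor == "risk", ]
  expect_gt(r$hr, exp(0.7) * 0.8)
  expect_lt(r$hr, exp(0.7) * 1.2)
  expect_true(r$lower < r$hr && r$hr < r$upper)
  expect_lt(r$p_lrt, 1e-6)
  expect_gt(tab$p_lrt[tab$factor == "noise"], 0.001)

  # two-level factors are coded against the reference level
  grp <- factor(ifelse(x > 0, "hi", "lo"), levels = c("lo", "hi"))
  tf <- hazard_ratio_table(data.frame(grp = grp), surv$pfs_days, surv$event)
  expect_gt(tf$hr, 1)

  # >2 levels is flagged, not fatal
  t3 <- hazard_ratio_table(
    data.frame(g3 = sample(c("a", "b", "c"), n, TRUE)),
    surv$pfs_days, surv$event)
  expect_true(is.na(t3$hr))
  expect_match(t3$note, "2 levels")
})

test_that("baseline chi-square matches the textbook 2x2 statistic", {
  # cohort A: 16 male / 16 female; cohort B: 17 male / 14 female
  clin <- data.frame(
    patient_id = sprintf("P%02d", 1:63),
    sex = c(rep("male", 16), rep("female", 16), rep("male", 17),
            rep("female", 14)),
    age_years = 50, smoking = "nonsmoker",
    pfs_days = 100, event = 1,
    cohort_label = rep(c("A", "B"), c(32, 31)))
  out <- compare_baseline(clin, characteristics = "sex")
  tab <- table(clin$cohort_label, clin$sex)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_hand <- sum((tab - expected)^2 / expected)
  expect_equal(out$statistic, chi_hand, tolerance = 1e-12)
  expect_equal(out$p, pchisq(chi_hand, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$flag, "")

  expect_error(compare_baseline(transform(clin, cohort_label = "A")), "two")
})

test_that("fit_signature exposes coefficients, cutoff and scores coherently", {
  set.seed(63)
  n <- 90
  x <- scale(matrix(rnorm(n * 2), n, 2))
  lp <- x[, 1] - 0.8 * x[, 2]
  surv <- simulate_survival(lp, seed = 65)
  feats <- data.frame(patient_id = sprintf("P%03d", 1:n), fa = x[, 1],
                      fb = x[, 2])
  clin <- mk_clinical(n, surv$pfs_days, surv$event)
  m <- fit_signature(feats, clin)
  expect_s3_class(m, "radiomic_signature")
  expect_named(coef(m), c("fa", "fb"))
  expect_gt(coef(m)[["fa"]], 0)
  expect_lt(coef(m)[["fb"]], 0)
  # predict() reproduces the training linear predictors
  expect_equal(unname(predict(m, feats)), unname(m$train_scores),
               tolerance = 1e-10)
  expect_equal(m$cutoff, median(m$train_scores))
  g <- stratify(m)
  expect_equal(levels(g), c("low", "high"))
  expect_equal(sum(g == "high"), n / 2)
  # scores exactly at the cutoff fall in the low-risk group
  expect_equal(as.character(stratify(m, m$cutoff)), "low")

  expect_error(predict(m, feats[, 1:2]), "lacks signature feature")
  expect_error(fit_signature(transform(feats, fa = 1), clin), "constant")
  clin0 <- clin; clin0$event <- 0L
  expect_error(fit_signature(feats, clin0), "no observed events")
})

test_that("clinical and combined models screen covariates at alpha", {
  set.seed(67)
  n <- 160
  age <- round(runif(n, 35, 80))
  z_age <- as.numeric(scale(age))
  sig <- rnorm(n)
  surv <- simulate_survival(0.9 * z_age + 0.8 * sig, seed = 69)
  clin <- mk_clinical(n, surv$pfs_days, surv$event)
  clin$age_years <- age
  half <- seq_len(n / 2)
  cc <- clinical_and_combined_models(clin[half, ], clin[-half, ],
                                     sig[half], sig[-half])
  expect_true("age_years" %in% cc$selected)
  expect_s3_class(cc$combined_model, "coxph")
  expect_true("signature" %in% names(coef(cc$combined_model)))
  expect_gt(cc$cindex$signature[["validation"]], 0.5)
  expect_gt(cc$cindex$combined[["validation"]],
            cc$cindex$clinical[["validation"]] - 0.05)

  # impossible screening level: falls back to signature-only combined model
  cc0 <- clinical_and_combined_models(clin[half, ], clin[-half, ],
                                      sig[half], sig[-half], alpha = 1e-12)
  expect_length(cc0$selected, 0)
  expect_match(cc0$note, "no clinical covariate")
  expect_true(all(is.na(cc0$cindex$clinical)))
})

test_that("evaluate_signature assembles a coherent two-cohort report", {
  set.seed(71)
  n <- 120
  x <- scale(matrix(rnorm(n * 2), n, 2))
  lp <- 1.2 * x[, 1] + 0.5 * x[, 2]
  surv <- simulate_survival(lp, seed = 73)
  feats <- data.frame(patient_id = sprintf("P%03d", 1:n), fa = x[, 1],
                      fb = x[, 2])
  clin <- mk_clinical(n, surv$pfs_days, surv$event)
  tr <- seq_len(n / 2)
  m <- fit_signature(feats[tr, ], clin[tr, ])
  ev <- evaluate_signature(
    m, cohorts = list(train = list(features = feats[tr, ], clinical = clin[tr, ]),
                      validation = list(features = feats[-tr, ],
                                        clinical = clin[-tr, ])),
    n_boot = 100, seed = 5)
  expect_s3_class(ev, "signature_evaluation")
  expect_named(ev, c("train", "validation"))
  v <- ev$validation
  expect_equal(v$n, n / 2)
  expect_named(v$median_pfs, c("low", "high"))
  expect_gt(v$cindex$cindex, 0.6)
  expect_lt(v$logrank$p, 0.05)
  expect_equal(v$logrank$rho, 1)
  expect_equal(v$hr$factor, "signature_per_sd")
  # high-risk group progresses faster: its median is reached and smaller
  # (the low-risk median can legitimately stay unreached under censoring)
  expect_true(v$km$high$median_reached)
  expect_true(!v$km$low$median_reached ||
                v$median_pfs[["high"]] < v$median_pfs[["low"]])
  expect_output(print(ev), "cohort validation")
})
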