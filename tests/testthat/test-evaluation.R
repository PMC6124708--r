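test_that("confusion counts partition evaluable records at inclusive cut-offs", {
  cm <- confusion_counts(c(4, 4, 2, 2), c(40, 10, 40, 10), 3, 30)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(1, 1, 1, 1))
  expect_equal(cm$n, 4)

  # all scores below the cut-off -> no predicted positives
  low <- confusion_counts(c(1, 2), c(40, 10), 3, 30)
  expect_equal(low$tp + low$fp, 0)

  # a score exactly at the cut-off is predicted positive
  at <- confusion_counts(3.7, 40, 3.7, 30)
  expect_equal(at$tp, 1)
  # an AHI exactly at its cut-off is diseased
  expect_equal(confusion_counts(5, 30, 3, 30)$tp, 1)

  # rows lacking a score or AHI are excluded and counted
  miss <- confusion_counts(c(4, NA, 2), c(40, 10, NA), 3, 30)
  expect_equal(miss$n, 1)
  expect_equal(miss$n_excluded, 2)
  expect_error(confusion_counts(NA, 40, 3, 30),
               class = "sasscreen_empty_input_error")
})

test_that("metrics reproduce hand ratios and flag undefined denominators", {
  perfect <- classification_metrics(as_confusion(1, 0, 0, 1))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  m <- classification_metrics(as_confusion(1386, 591, 285, 331))
  expect_equal(m$sensitivity, 1386 / 1671, tolerance = 1e-12)
  expect_equal(m$specificity, 331 / 922, tolerance = 1e-12)
  expect_equal(m$ppv, 1386 / 1977, tolerance = 1e-12)
  expect_equal(m$npv, 331 / 616, tolerance = 1e-12)
  expect_equal(m$predicted_prevalence, 1977 / 2593, tolerance = 1e-12)

  # no predicted positives: PPV undefined, everything else still reported
  expect_warning(part <- classification_metrics(as_confusion(0, 0, 5, 5)),
                 class = "sasscreen_undefined_metric")
  expect_true(is.na(part$ppv))
  expect_equal(part$specificity, 1)
})

test_that("PPV is Bayes-consistent with sensitivity, specificity and prevalence", {
  withr::with_seed(7, {
    for (i in 1:25) {
      cm <- as_confusion(sample(1:50, 1), sample(1:50, 1),
                         sample(1:50, 1), sample(1:50, 1))
      m <- classification_metrics(cm)
      p <- (cm$tp + cm$fn) / cm$n
      expect_equal(m$ppv,
                   m$sensitivity * p / (m$sensitivity * p + (1 - m$specificity) * (1 - p)),
                   tolerance = 1e-12)
    }
  })
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting", {
  # perfectly separated classes
  expect_equal(roc_auc(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # ties only
  expect_equal(roc_auc(c(5, 5, 5, 5), c(FALSE, FALSE, TRUE, TRUE)), 0.5)
  # 3 of 4 diseased/non-diseased pairs correctly ordered
  expect_equal(roc_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)), 0.75)

  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)),
               class = "sasscreen_degenerate_error")

  withr::with_seed(11, {
    for (i in 1:100) {
      sl <- random_scored_labels(200)
      expect_equal(roc_auc(sl$score, sl$disease),
                   auc_pair_oracle(sl$score, sl$disease), tolerance = 1e-12)
      # negating all scores maps AUC to 1 - AUC
      expect_equal(roc_auc(-sl$score, sl$disease),
                   1 - roc_auc(sl$score, sl$disease), tolerance = 1e-12)
    }
  })
})

test_that("ROC curves run from (0,0) to (1,1) and agree with pROC", {
  sl <- withr::with_seed(5, random_scored_labels(150))
  curve <- roc_curve(sl$score, sl$disease)
  expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
  expect_equal(c(dplyr::last(curve$fpr), dplyr::last(curve$tpr)), c(1, 1))
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))

  ref <- pROC::roc(sl$disease, sl$score, quiet = TRUE, direction = "<")
  expect_equal(attr(curve, "auc"), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("DeLong intervals match the independent reference implementation", {
  withr::with_seed(19, {
    for (i in 1:5) {
      n <- 120
      score <- rnorm(n)
      disease <- runif(n) < plogis(score)
      if (!any(disease) || all(disease)) next
      ci <- auc_ci(score, disease, method = "delong")
      ref <- as.numeric(pROC::ci.auc(pROC::roc(disease, score, quiet = TRUE,
                                               direction = "<"),
                                     method = "delong"))
      expect_equal(c(ci$lower, ci$upper), ref[c(1, 3)], tolerance = 1e-9)
      expect_true(ci$lower <= ci$auc && ci$auc <= ci$upper)
    }
  })
})

test_that("bootstrap intervals are seed-reproducible and near the DeLong interval", {
  withr::with_seed(23, {
    score <- rnorm(500)
    disease <- runif(500) < plogis(1.5 * score)
  })
  b1 <- auc_ci(score, disease, method = "bootstrap", seed = 99)
  b2 <- auc_ci(score, disease, method = "bootstrap", seed = 99)
  expect_identical(b1, b2)
  dl <- auc_ci(score, disease, method = "delong")
  expect_lt(abs(b1$lower - dl$lower), 0.02)
  expect_lt(abs(b1$upper - dl$upper), 0.02)
  expect_error(auc_ci(score, disease, method = "bootstrap"),
               class = "sasscreen_config_error")
  expect_error(auc_ci(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               class = "sasscreen_degenerate_error")
})

test_that("cut-off sweeps are monotone with the smallest-gap crossover rule", {
  cohort <- suppressMessages(generate_cohort(westro_cohort_spec(n = 2000, seed = 13)))
  s <- score_sas(cohort)$sas_score
  sw <- cutoff_sweep(s, cohort$ahi)
  expect_true(all(diff(sw$sensitivity) <= 0))
  expect_true(all(diff(sw$specificity) >= 0))
  expect_true(sweep_crossover(sw) %in% sw$cutoff)

  # cut-off below every score -> sensitivity 1; above every score -> specificity 1
  ends <- cutoff_sweep(s, cohort$ahi, cutoffs = c(0.5, 99))
  expect_equal(ends$sensitivity[1], 1)
  expect_equal(ends$specificity[2], 1)

  # a one-point grid is its own crossover
  one <- cutoff_sweep(s, cohort$ahi, cutoffs = 3.7)
  expect_equal(nrow(one), 1)
  expect_equal(sweep_crossover(one), 3.7)

  # ties break to the smallest cut-off achieving the minimal gap
  flat <- cutoff_sweep(c(1, 10), c(40, 10), cutoffs = c(2, 3, 4))
  expect_equal(sweep_crossover(flat), 2)

  expect_error(cutoff_sweep(s, cohort$ahi, cutoffs = numeric()),
               class = "sasscreen_empty_input_error")
  expect_error(cutoff_sweep(s, cohort$ahi, cutoffs = c(3, 3)),
               class = "sasscreen_config_error")
})

test_that("cohort evaluation composes scoring, confusion, metrics and AUC", {
  cohort <- suppressMessages(generate_cohort(westro_cohort_spec(n = 1500, seed = 17)))
  perf <- evaluate_cohort(cohort, "sas", score_cutoff = 3, ahi_cutoff = 30)
  g <- glance(perf)
  props <- unlist(g[c("sensitivity", "specificity", "ppv", "npv",
                      "predicted_prevalence", "prevalence", "auc")])
  expect_true(all(props >= 0 & props <= 1))
  expect_true(g$auc_low <= g$auc && g$auc <= g$auc_high)
  expect_equal(g$n, 1500)

  # a score that ranks patients exactly as AHI does gives AUC 1
  ranked <- dplyr::mutate(cohort, ahi_rank = rank(ahi))
  expect_equal(roc_auc(ranked$ahi_rank, ranked$ahi >= 30), 1)

  # records missing AHI or score inputs are excluded and counted
  holed <- cohort
  holed$ahi[1:10] <- NA
  holed$ess[11:15] <- NA
  perf2 <- suppressMessages(evaluate_cohort(holed, "sas"))
  expect_equal(perf2$n_excluded, 15)
  expect_equal(perf2$metrics$n, 1485)

  expect_error(evaluate_cohort(dplyr::select(cohort, -ahi), "sas"),
               class = "sasscreen_missing_field_error")
  single <- dplyr::mutate(cohort[1:20, ], ahi = 50)
  expect_error(evaluate_cohort(single, "sas"),
               class = "sasscreen_degenerate_error")
})

test_that("tidiers expose performance results in broom-shaped tibbles", {
  cohort <- suppressMessages(generate_cohort(westro_cohort_spec(n = 800, seed = 29)))
  perf <- evaluate_cohort(cohort, "nosas")
  td <- tidy(perf)
  expect_equal(td$metric[7], "auc")
  expect_equal(td$estimate[td$metric == "auc"], perf$auc$auc)
  expect_equal(nrow(glance(perf)), 1)
  expect_equal(sum(tidy(perf$confusion)$count), perf$metrics$n)
  sw <- cutoff_sweep(score_sas(cohort)$sas_score, cohort$ahi)
  expect_equal(nrow(tidy(sw)), 2 * nrow(sw))
  expect_equal(glance(sw)$crossover_cutoff, sweep_crossover(sw))
})

test_that("autoplot methods return ggplot objects", {
  cohort <- suppressMessages(generate_cohort(westro_cohort_spec(n = 300, seed = 3)))
  s <- score_sas(cohort)$sas_score
  expect_s3_class(autoplot(roc_curve(s, cohort$ahi >= 30)), "ggplot")
  expect_s3_class(autoplot(cutoff_sweep(s, cohort$ahi)), "ggplot")
  expect_s3_class(autoplot(subscore_table("bmi", 20:40)), "ggplot")
  card <- scorecard_grid(c(20, 30, 40), c(35, 40, 45), c(110, 140, 170),
                         c(0, 11, 24), sex = "male")
  expect_s3_class(autoplot(card), "ggplot")
})
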