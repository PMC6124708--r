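#' Confusion matrix at a score / AHI cut-off pair
#'
#' Cross-classifies screening prediction against the reference standard:
#' a patient is predicted positive when `score >= score_cutoff` (the
#' cut-off is inclusive) and diseased when `ahi >= ahi_cutoff`. Rows with a
#' missing score or AHI are excluded and counted.
#'
#' @param score Numeric vector of screening score values.
#' @param ahi Numeric vector of apnea-hypopnea-index values (events/h),
#'   aligned with `score`.
#' @param score_cutoff Screening positivity cut-off (default 3, the
#'   Low/Mild band boundary).
#' @param ahi_cutoff Diagnosis cut-off in events/h (default 30, clinically
#'   significant disease).
#' @return A list of class `osa_confusion` with integer counts `tp`, `fp`,
#'   `fn`, `tn`, the two cut-offs, `n` (evaluable records) and `n_excluded`.
#' @export
#' @examples
#' confusion_counts(c(4, 4, 2, 2), c(40, 10, 40, 10), 3, 30)
confusion_counts <- function(score, ahi, score_cutoff = 3, ahi_cutoff = 30) {
  if (length(score) != length(ahi)) {
    stop_validation("score and ahi must be aligned vectors of the same length")
  }
  ok <- !is.na(score) & !is.na(ahi)
  n_excluded <- sum(!ok)
  score <- score[ok]
  ahi <- ahi[ok]
  if (length(score) == 0) {
    stop_empty("no evaluable records: every row lacks a score or an AHI")
  }
  pred <- score >= score_cutoff
  dis <- ahi >= ahi_cutoff
  structure(list(
    tp = sum(pred & dis), fp = sum(pred & !dis),
    fn = sum(!pred & dis), tn = sum(!pred & !dis),
    score_cutoff = score_cutoff, ahi_cutoff = ahi_cutoff,
    n = length(score), n_excluded = n_excluded
  ), class = "osa_confusion")
}

#' Build a confusion object from printed counts
#'
#' Wraps externally reported true/false positive/negative counts (e.g. a
#' published classification table) so they can be fed to
#' [classification_metrics()].
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @param score_cutoff,ahi_cutoff Optional cut-offs the counts were obtained
#'   at, recorded for provenance.
#' @return An `osa_confusion` object.
#' @export
as_confusion <- function(tp, fp, fn, tn, score_cutoff = NA_real_, ahi_cutoff = NA_real_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_validation("confusion counts must be non-negative integers")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 score_cutoff = score_cutoff, ahi_cutoff = ahi_cutoff,
                 n = tp + fp + fn + tn, n_excluded = 0L),
            class = "osa_confusion")
}

#' @export
print.osa_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (score >= %s, AHI >= %s; n = %d, excluded = %d)\n",
              format(x$score_cutoff), format(x$ahi_cutoff), x$n, x$n_excluded))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("pred+", "pred-"), c("disease+", "disease-")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den, name) {
  if (den == 0) {
    warn(sprintf("%s is undefined: its denominator is zero", name),
         class = "sasscreen_undefined_metric")
    return(NA_real_)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)` and predicted
#' prevalence `(tp+fp)/n`. A zero denominator yields `NA` for that metric
#' only, with a warning; the others are still returned.
#'
#' @param cm An `osa_confusion` object from [confusion_counts()] or
#'   [as_confusion()].
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `predicted_prevalence`, `prevalence` (disease
#'   prevalence `(tp+fn)/n`) and `n`.
#' @export
#' @examples
#' classification_metrics(as_confusion(tp = 1386, fp = 591, fn = 285, tn = 331))
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "osa_confusion"))
  tibble(
    sensitivity = safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = safe_ratio(cm$tn, cm$tn + cm$fp, "specificity"),
    ppv = safe_ratio(cm$tp, cm$tp + cm$fp, "ppv"),
    npv = safe_ratio(cm$tn, cm$tn + cm$fn, "npv"),
    predicted_prevalence = safe_ratio(cm$tp + cm$fp, cm$n, "predicted_prevalence"),
    prevalence = safe_ratio(cm$tp + cm$fn, cm$n, "prevalence"),
    n = cm$n
  )
}

check_two_classes <- function(disease) {
  if (any(is.na(disease))) stop_validation("disease labels must not be missing")
  if (!any(disease) || all(disease)) {
    stop_degenerate("ROC analysis needs both diseased and non-diseased records")
  }
}

#' Empirical ROC curve
#'
#' Sweeps every distinct score value as a positivity threshold (prediction
#' positive at `score >= threshold`) and records the false- and
#' true-positive rates. The curve starts at (0, 0) (threshold above every
#' score) and ends at (1, 1).
#'
#' @param score Numeric screening score values (higher = more suspicious).
#' @param disease Logical disease labels aligned with `score` (or anything
#'   coercible; AHI-based labels are typically `ahi >= 30`).
#' @return A tibble of class `osa_roc` with columns `threshold`, `fpr`,
#'   `tpr`, ordered by increasing `fpr`; the AUC is in the `"auc"`
#'   attribute.
#' @export
roc_curve <- function(score, disease) {
  disease <- as.logical(disease)
  ok <- !is.na(score)
  score <- score[ok]
  disease <- disease[ok]
  check_two_classes(disease)
  n_pos <- sum(disease)
  n_neg <- sum(!disease)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & disease) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & !disease) / n_neg, numeric(1))
  out <- tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  attr(out, "auc") <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) + utils::tail(out$tpr, -1)) / 2)
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  class(out) <- c("osa_roc", class(out))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC curve over all distinct score
#' thresholds. This equals the Mann-Whitney probability that a diseased
#' record outscores a non-diseased one, with ties credited 1/2.
#'
#' @inheritParams roc_curve
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))
roc_auc <- function(score, disease) {
  attr(roc_curve(score, disease), "auc")
}

# DeLong structural components: per-record placement values whose variances
# give the asymptotic variance of the empirical (Mann-Whitney) AUC.
delong_variance <- function(score, disease) {
  x <- score[disease]   # diseased
  y <- score[!disease]  # non-diseased
  m <- length(x)
  n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  auc <- mean(v10)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, var = var_auc)
}

#' Confidence interval for the AUC
#'
#' DeLong's asymptotic interval (default) or a class-stratified bootstrap
#' percentile interval. Both keep the point AUC inside the interval; the
#' DeLong interval is clipped to \[0, 1\].
#'
#' @inheritParams roc_curve
#' @param method `"delong"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap (required for
#'   `method = "bootstrap"` so results are reproducible).
#' @return A list with `auc`, `lower`, `upper`, `method` and `level`.
#' @export
auc_ci <- function(score, disease, method = c("delong", "bootstrap"),
                   level = 0.95, boot = 2000, seed = NULL) {
  method <- match.arg(method)
  disease <- as.logical(disease)
  ok <- !is.na(score)
  score <- score[ok]
  disease <- disease[ok]
  check_two_classes(disease)
  if (sum(disease) < 2 || sum(!disease) < 2) {
    stop_degenerate("AUC confidence intervals need at least 2 records per class")
  }
  auc <- roc_auc(score, disease)
  if (method == "delong") {
    dl <- delong_variance(score, disease)
    z <- qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(dl$var)
    lower <- max(0, dl$auc - half)
    upper <- min(1, dl$auc + half)
  } else {
    if (is.null(seed)) stop_config("bootstrap confidence intervals require a seed")
    pos <- which(disease)
    neg <- which(!disease)
    boot_auc <- withr::with_seed(seed, vapply(seq_len(boot), function(i) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      roc_auc(score[idx], disease[idx])
    }, numeric(1)))
    qs <- stats::quantile(boot_auc, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    lower <- min(qs[1], auc)
    upper <- max(qs[2], auc)
  }
  list(auc = auc, lower = lower, upper = upper, method = method, level = level)
}

#' Sensitivity-specificity sweep over score cut-offs
#'
#' Evaluates sensitivity and specificity at each cut-off of an increasing
#' grid (prediction positive at `score >= cutoff`, disease at
#' `ahi >= ahi_cutoff`). As the cut-off rises, sensitivity is
#' non-increasing and specificity non-decreasing; both are verified on
#' every run. The crossover cut-off is the grid point minimising
#' `|sensitivity - specificity|`, taking the smallest such point on ties —
#' the operating point where the two error rates balance.
#'
#' @inheritParams confusion_counts
#' @param cutoffs Strictly increasing numeric grid of score cut-offs
#'   (default 2.5 to 6 in steps of 0.05).
#' @return A tibble of class `osa_sweep` with columns `cutoff`,
#'   `sensitivity`, `specificity`; the crossover cut-off is in the
#'   `"crossover"` attribute (also via [sweep_crossover()]).
#' @export
cutoff_sweep <- function(score, ahi, cutoffs = seq(2.5, 6, by = 0.05),
                         ahi_cutoff = 30) {
  if (length(cutoffs) == 0) stop_empty("cut-off grid must be non-empty")
  if (any(diff(cutoffs) <= 0)) {
    stop_config("cut-off grid must be strictly increasing")
  }
  rows <- purrr::map_dfr(cutoffs, function(ct) {
    cm <- confusion_counts(score, ahi, ct, ahi_cutoff)
    # only the two sweep metrics are needed; at extreme cut-offs the
    # predictive values are undefined and would warn spuriously
    tibble(cutoff = ct,
           sensitivity = safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
           specificity = safe_ratio(cm$tn, cm$tn + cm$fp, "specificity"))
  })
  if (isTRUE(is.unsorted(-rows$sensitivity)) || isTRUE(is.unsorted(rows$specificity))) {
    abort("internal invariant violated: sweep metrics are not monotone in the cut-off",
          class = "sasscreen_internal_error")
  }
  gap <- abs(rows$sensitivity - rows$specificity)
  attr(rows, "crossover") <- rows$cutoff[which.min(gap)]
  attr(rows, "ahi_cutoff") <- ahi_cutoff
  class(rows) <- c("osa_sweep", class(rows))
  rows
}

#' @rdname cutoff_sweep
#' @param x An `osa_sweep` object.
#' @export
sweep_crossover <- function(x) {
  stopifnot(inherits(x, "osa_sweep"))
  attr(x, "crossover")
}

#' Evaluate a screening score on a cohort
#'
#' End-to-end diagnostic-performance evaluation: scores the cohort with the
#' chosen instrument, cross-classifies against the AHI reference standard at
#' the given cut-offs, and reports sensitivity, specificity, predictive
#' values, predicted prevalence and the AUC with its confidence interval.
#' Records missing any input the score needs, or missing AHI, are excluded
#' and counted.
#'
#' @param data A cohort tibble in canonical layout with an `ahi` column.
#' @param score_name `"sas"`, `"stop_bang"` or `"nosas"`.
#' @param score_cutoff Positivity cut-off on the chosen score (defaults:
#'   3 for SAS, 3 for STOP-Bang, 8 for NoSAS — pass explicitly to
#'   override; the SAS cut-off 3.7 balances sensitivity and specificity).
#' @param ahi_cutoff Diagnosis cut-off in events/h (default 30; the
#'   conventional presets are 5, 10, 15, 20, 30 and 45).
#' @param config A [comparator_config()] for the comparator scores.
#' @param ci_method,boot,seed Passed to [auc_ci()].
#' @return A list of class `osa_performance` with elements `score_name`,
#'   `metrics` (one-row tibble), `auc` (list from [auc_ci()]),
#'   `confusion`, `roc` and `n_excluded`.
#' @export
evaluate_cohort <- function(data, score_name = c("sas", "stop_bang", "nosas"),
                            score_cutoff = NULL, ahi_cutoff = 30,
                            config = comparator_config(),
                            ci_method = "delong", boot = 2000, seed = NULL) {
  score_name <- match.arg(score_name)
  if (!"ahi" %in% names(data)) {
    stop_missing_field("ahi", "the reference standard is required for evaluation")
  }
  if (is.null(score_cutoff)) {
    score_cutoff <- switch(score_name, sas = 3, stop_bang = config$stop_bang_positive_at,
                           nosas = config$nosas_positive_at)
  }
  scored <- switch(score_name,
    sas = score_sas(data, na_action = "keep"),
    stop_bang = {
      d <- data
      d$hypertension <- resolve_hypertension(data, config)
      complete <- !is.na(d$sex) & !is.na(d$age) & !is.na(d$bmi) & !is.na(d$neck_cm) &
        !is.na(d$hypertension) & !is.na(d$snoring) & !is.na(d$tiredness) &
        !is.na(d$observed_apnea)
      d$score_value <- NA_real_
      if (any(complete)) {
        d$score_value[complete] <- score_stop_bang(d[complete, ], config)$stop_bang
      }
      d
    },
    nosas = {
      d <- data
      complete <- !is.na(d$sex) & !is.na(d$age) & !is.na(d$bmi) & !is.na(d$neck_cm) &
        !is.na(d$snoring)
      d$score_value <- NA_real_
      if (any(complete)) {
        d$score_value[complete] <- score_nosas(d[complete, ], config)$nosas
      }
      d
    }
  )
  values <- if (score_name == "sas") scored$sas_score else scored$score_value
  cm <- confusion_counts(values, data$ahi, score_cutoff, ahi_cutoff)
  if (cm$n_excluded > 0) {
    inform(sprintf("%d record(s) excluded for missing score inputs or AHI", cm$n_excluded))
  }
  ok <- !is.na(values) & !is.na(data$ahi)
  disease <- data$ahi[ok] >= ahi_cutoff
  roc <- roc_curve(values[ok], disease)
  auc <- auc_ci(values[ok], disease, method = ci_method, boot = boot, seed = seed)
  structure(list(
    score_name = score_name,
    metrics = classification_metrics(cm),
    auc = auc,
    confusion = cm,
    roc = roc,
    n_excluded = cm$n_excluded
  ), class = "osa_performance")
}

#' @export
print.osa_performance <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Diagnostic performance of %s (score >= %s vs AHI >= %s)\n",
              x$score_name, format(x$confusion$score_cutoff),
              format(x$confusion$ahi_cutoff)))
  cat(sprintf("  n = %d (excluded %d)\n", m$n, x$n_excluded))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv))
  cat(sprintf("  predicted prevalence %.1f%% (true %.1f%%)\n",
              100 * m$predicted_prevalence, 100 * m$prevalence))
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f, %s)\n",
              x$auc$auc, round(100 * x$auc$level), x$auc$lower, x$auc$upper,
              x$auc$method))
  invisible(x)
}
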