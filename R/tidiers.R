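#' Tidy a diagnostic-performance result
#'
#' @param x An `osa_performance` from [evaluate_cohort()].
#' @param ... Unused.
#' @return A tibble with one row per metric: `metric`, `estimate` and,
#'   for the AUC, `conf.low`/`conf.high`.
#' @method tidy osa_performance
#' @export
tidy.osa_performance <- function(x, ...) {
  m <- x$metrics
  tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv",
               "predicted_prevalence", "prevalence", "auc"),
    estimate = c(m$sensitivity, m$specificity, m$ppv, m$npv,
                 m$predicted_prevalence, m$prevalence, x$auc$auc),
    conf.low = c(rep(NA_real_, 6), x$auc$lower),
    conf.high = c(rep(NA_real_, 6), x$auc$upper)
  )
}

#' Glance at a diagnostic-performance result
#'
#' @inheritParams tidy.osa_performance
#' @return A one-row tibble: score name, cut-offs, all metrics, AUC with
#'   CI, `n` and `n_excluded`.
#' @method glance osa_performance
#' @export
glance.osa_performance <- function(x, ...) {
  m <- x$metrics
  tibble(
    score_name = x$score_name,
    score_cutoff = x$confusion$score_cutoff,
    ahi_cutoff = x$confusion$ahi_cutoff,
    sensitivity = m$sensitivity, specificity = m$specificity,
    ppv = m$ppv, npv = m$npv,
    predicted_prevalence = m$predicted_prevalence,
    prevalence = m$prevalence,
    auc = x$auc$auc, auc_low = x$auc$lower, auc_high = x$auc$upper,
    n = m$n, n_excluded = x$n_excluded
  )
}

#' Tidy a confusion matrix
#'
#' @param x An `osa_confusion`.
#' @param ... Unused.
#' @return A four-row tibble with `prediction`, `disease` and `count`.
#' @method tidy osa_confusion
#' @export
tidy.osa_confusion <- function(x, ...) {
  tibble(
    prediction = c("positive", "positive", "negative", "negative"),
    disease = c("positive", "negative", "positive", "negative"),
    count = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' Tidy a cut-off sweep
#'
#' @param x An `osa_sweep` from [cutoff_sweep()].
#' @param ... Unused.
#' @return A long tibble with `cutoff`, `metric`, `value`.
#' @method tidy osa_sweep
#' @export
tidy.osa_sweep <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), c("sensitivity", "specificity"),
                      names_to = "metric", values_to = "value")
}

#' Glance at a cut-off sweep
#'
#' @inheritParams tidy.osa_sweep
#' @return A one-row tibble with the crossover cut-off and the metrics
#'   attained there.
#' @method glance osa_sweep
#' @export
glance.osa_sweep <- function(x, ...) {
  cross <- attr(x, "crossover")
  at <- which(x$cutoff == cross)[1]
  tibble(
    crossover_cutoff = cross,
    sensitivity = x$sensitivity[at],
    specificity = x$specificity[at],
    ahi_cutoff = attr(x, "ahi_cutoff"),
    n_cutoffs = nrow(x)
  )
}
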