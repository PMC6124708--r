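# Reproducible-run front end: one declarative config drives every command.
# These run_*() functions are what the inst/cli/sasscreen.R script wraps;
# they are ordinary package functions so the whole surface is testable
# without spawning processes.

#' Assemble a run configuration
#'
#' Collects every setting the pipeline commands understand, from an
#' optional YAML file plus overrides (overrides win key by key). Unknown
#' keys are rejected so typos surface instead of being ignored.
#'
#' @param path Optional YAML config file.
#' @param ... Individual overrides (same keys as the file): `input`,
#'   `mapping` (named list: canonical field -> source column), `delim`,
#'   `male_code`, `score` (`"sas"`, `"stop_bang"`, `"nosas"`),
#'   `score_cutoff`, `ahi_cutoff`, `sweep_from`, `sweep_to`, `sweep_by`,
#'   `ci_method`, `boot`, `seed`, `out_dir`, `figures` (logical),
#'   `comparator` (list passed to [comparator_config()]), `simulate`
#'   (list passed to [cohort_spec()]), `calibrate` (logical),
#'   `bins` (list with `bmi`, `nc`, `bp`, `ess` break vectors and `sex`).
#' @return A list of class `run_config` with defaults filled in.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    input = NULL, mapping = NULL, delim = NULL, male_code = "1",
    score = "sas", score_cutoff = NULL, ahi_cutoff = 30,
    sweep_from = 2.5, sweep_to = 6, sweep_by = 0.05,
    ci_method = "delong", boot = 2000, seed = 1L,
    out_dir = ".", figures = FALSE,
    comparator = list(), simulate = list(), calibrate = FALSE,
    bins = NULL
  )
  from_file <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- list(...)
  unknown <- setdiff(c(names(from_file), names(overrides)), names(defaults))
  if (length(unknown) > 0) {
    stop_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), overrides)
  if (!is.null(cfg$score_cutoff) && cfg$score_cutoff <= 0) {
    stop_config("score_cutoff must be positive")
  }
  if (cfg$ahi_cutoff <= 0) stop_config("ahi_cutoff must be positive")
  if (cfg$sweep_by <= 0 || cfg$sweep_to <= cfg$sweep_from) {
    stop_config("sweep grid must be increasing (sweep_from < sweep_to, sweep_by > 0)")
  }
  class(cfg) <- "run_config"
  cfg
}

cfg_input <- function(config) {
  if (is.null(config$input)) stop_config("config key 'input' is required for this command")
  mapping <- config$mapping
  if (is.list(mapping)) mapping <- unlist(mapping)
  read_cohort(config$input, mapping = mapping, delim = config$delim,
              male_code = config$male_code, strict = FALSE)
}

cfg_comparator <- function(config) {
  do.call(comparator_config, config$comparator)
}

out_path <- function(config, name) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$out_dir, name)
}

write_rejects <- function(problems, path) {
  readr::write_csv(problems, path)
  invisible(path)
}

#' Score every patient in a cohort file
#'
#' Reads the configured input, scores each valid row with the SAS score,
#' and writes one row per patient (id, the four sub-scores, the score and
#' its risk band) to `scores.csv` in the output directory. Rows failing
#' validation or missing a required measurement are not scored; they are
#' written to `rejects.csv` with row index, field and reason, so partial
#' data degrades gracefully instead of aborting the run.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `scores` (tibble), `rejects` (tibble)
#'   and the two output paths.
#' @export
run_score <- function(config) {
  cohort <- cfg_input(config)
  problems <- attr(cohort, "problems")
  if (nrow(cohort) == 0) {
    warn("input cohort has no scoreable rows; writing a header-only score table")
  }
  scored <- score_sas(cohort, na_action = "keep")
  incomplete <- is.na(scored$sas_score)
  miss <- purrr::map_dfr(which(incomplete), function(i) {
    fields <- c("sex", "bmi", "neck_cm", "sys_bp", "ess")
    bad <- fields[vapply(fields, function(f) is.na(cohort[[f]][i]), logical(1))]
    tibble(row = i, field = paste(bad, collapse = ";"),
           problem = "missing required measurement; row not scored")
  })
  rejects <- dplyr::bind_rows(problems, miss)
  table <- scored[!incomplete,
                  c("id", "sub_bmi", "sub_nc", "sub_bp", "sub_ess",
                    "sas_score", "sas_band")]
  scores_path <- out_path(config, "scores.csv")
  readr::write_csv(table, scores_path)
  rejects_path <- out_path(config, "rejects.csv")
  write_rejects(rejects, rejects_path)
  if (nrow(rejects) > 0) {
    inform(sprintf("%d row(s) rejected; details in %s", length(unique(rejects$row)),
                   rejects_path))
  }
  invisible(list(scores = table, rejects = rejects,
                 scores_path = scores_path, rejects_path = rejects_path))
}

#' Evaluate a screening score against the AHI reference
#'
#' Runs [evaluate_cohort()] on the configured input and writes the
#' performance report (`report.yaml`, one key per metric) and the
#' underlying confusion matrix (`confusion.csv`).
#'
#' @inheritParams run_score
#' @return Invisibly, the `osa_performance` object plus output paths.
#' @export
run_evaluate <- function(config) {
  cohort <- cfg_input(config)
  perf <- evaluate_cohort(cohort, score_name = config$score,
                          score_cutoff = config$score_cutoff,
                          ahi_cutoff = config$ahi_cutoff,
                          config = cfg_comparator(config),
                          ci_method = config$ci_method,
                          boot = config$boot, seed = config$seed)
  report_path <- out_path(config, "report.yaml")
  yaml::write_yaml(as.list(glance(perf)), report_path)
  confusion_path <- out_path(config, "confusion.csv")
  readr::write_csv(tidy(perf$confusion), confusion_path)
  invisible(list(performance = perf, report_path = report_path,
                 confusion_path = confusion_path))
}

#' Sweep score cut-offs on a cohort file
#'
#' Computes the sensitivity-specificity sweep of the configured score over
#' the configured grid and writes the grid (`sweep.csv`), the crossover
#' cut-off (`crossover.yaml`) and, when `figures` is enabled, the sweep
#' figure (`sweep.png`).
#'
#' @inheritParams run_score
#' @return Invisibly, the `osa_sweep` object plus output paths.
#' @export
run_sweep <- function(config) {
  cohort <- cfg_input(config)
  values <- score_values(cohort, config)
  grid <- seq(config$sweep_from, config$sweep_to, by = config$sweep_by)
  sw <- cutoff_sweep(values, cohort$ahi, cutoffs = grid,
                     ahi_cutoff = config$ahi_cutoff)
  sweep_path <- out_path(config, "sweep.csv")
  readr::write_csv(as_tibble(sw), sweep_path)
  cross_path <- out_path(config, "crossover.yaml")
  yaml::write_yaml(as.list(glance(sw)), cross_path)
  fig_path <- NULL
  if (isTRUE(config$figures)) {
    fig_path <- out_path(config, "sweep.png")
    ggplot2::ggsave(fig_path, autoplot(sw), width = 6, height = 4, dpi = 150)
  }
  invisible(list(sweep = sw, sweep_path = sweep_path,
                 crossover_path = cross_path, figure_path = fig_path))
}

score_values <- function(cohort, config) {
  switch(config$score,
    sas = score_sas(cohort, na_action = "keep")$sas_score,
    stop_bang = score_stop_bang(cohort, cfg_comparator(config))$stop_bang,
    nosas = score_nosas(cohort, cfg_comparator(config))$nosas,
    stop_config(sprintf("unknown score '%s'", config$score))
  )
}

#' Simulate a synthetic cohort to file
#'
#' Builds a [cohort_spec()] from the config (`simulate` keys override the
#' sleep-laboratory defaults of [westro_cohort_spec()]), optionally runs
#' [calibrate_prevalence()], generates the cohort and writes it
#' (`cohort.csv`) together with the generator report
#' (`generator_report.yaml`). Deterministic under the configured seed.
#'
#' @inheritParams run_score
#' @return Invisibly, the cohort tibble plus output paths.
#' @export
run_simulate <- function(config) {
  spec <- westro_cohort_spec(seed = config$seed)
  spec_args <- config$simulate
  if (length(spec_args) > 0 && (!is.list(spec_args) || is.null(names(spec_args)))) {
    stop_config("config key 'simulate' must be a named list of cohort-spec settings")
  }
  if (length(spec_args) > 0) {
    for (k in names(spec_args)) {
      if (!k %in% names(spec)) stop_config(sprintf("unknown simulate key '%s'", k))
      if (k %in% c("marginals", "clip")) {
        spec[[k]] <- utils::modifyList(spec[[k]], spec_args[[k]])
      } else if (k %in% c("loadings", "symptom_rates")) {
        v <- unlist(spec_args[[k]])
        spec[[k]][names(v)] <- v
      } else {
        spec[[k]] <- spec_args[[k]]
      }
    }
  }
  spec$seed <- as.integer(config$seed)
  validate_cohort_spec(spec)
  if (isTRUE(config$calibrate)) {
    spec <- calibrate_prevalence(spec)
  }
  cohort <- generate_cohort(spec)
  cohort_path <- out_path(config, "cohort.csv")
  write_cohort(cohort, cohort_path)
  report <- generator_report(cohort)
  report_path <- out_path(config, "generator_report.yaml")
  if (!is.null(report)) {
    yaml::write_yaml(list(
      realized = lapply(split(report$realized, report$realized$variable),
                        function(r) list(mean = r$mean, sd = r$sd)),
      prevalence_ahi_ge_30 = report$prevalence,
      male_frac = report$male_frac,
      symptom_rates = as.list(report$symptom_rates),
      hypertension_rate = report$hypertension_rate,
      spearman_sas_ahi = report$spearman_sas_ahi,
      clipped = as.list(report$clipped)
    ), report_path)
  }
  invisible(list(cohort = cohort, cohort_path = cohort_path,
                 report_path = report_path))
}

#' Summarise a cohort file
#'
#' @inheritParams run_score
#' @return Invisibly, the summary tibble and its output path
#'   (`summary.csv`).
#' @export
run_summarize <- function(config) {
  cohort <- cfg_input(config)
  s <- cohort_summary(cohort)
  path <- out_path(config, "summary.csv")
  readr::write_csv(as_tibble(s), path)
  invisible(list(summary = s, summary_path = path))
}

#' Render the severity scorecard to file
#'
#' @inheritParams run_score
#' @return Invisibly, the scorecard tibble and its output path
#'   (`scorecard.csv`; `scorecard.png` when figures are enabled).
#' @export
run_scorecard <- function(config) {
  bins <- config$bins
  if (is.null(bins)) {
    bins <- list(bmi = c(20, 25, 30, 35, 40, 50), nc = c(32, 36, 40, 44, 48, 52),
                 bp = c(100, 120, 140, 160, 180), ess = c(0, 6, 11, 16, 24),
                 sex = "female")
  }
  card <- scorecard_grid(bins$bmi, bins$nc, bins$bp, bins$ess, sex = bins$sex)
  path <- out_path(config, "scorecard.csv")
  readr::write_csv(as_tibble(card), path)
  fig_path <- NULL
  if (isTRUE(config$figures)) {
    fig_path <- out_path(config, "scorecard.png")
    ggplot2::ggsave(fig_path, autoplot(card), width = 9, height = 7, dpi = 150)
  }
  invisible(list(scorecard = card, scorecard_path = path, figure_path = fig_path))
}
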