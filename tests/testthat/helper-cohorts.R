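# Fixtures are built in code: small hand-written cohorts, a random-record
# generator for property tests, and an exhaustive pair-counting AUC oracle
# kept independent of the trapezoidal implementation it checks.

worked_example_patient <- function() {
  tibble::tibble(
    id = "p1", sex = "male", age = 49, bmi = 39, neck_cm = 46,
    sys_bp = 140, dia_bp = 85, ess = 8,
    hypertension = TRUE, snoring = TRUE, tiredness = FALSE,
    observed_apnea = FALSE, ahi = 42
  )
}

small_cohort <- function() {
  tibble::tibble(
    id = c("a", "b", "c"),
    sex = c("male", "female", "female"),
    age = c(60, 45, 52),
    bmi = c(36, 30, 28),
    neck_cm = c(44, 40, 38),
    sys_bp = c(150, 140, 120),
    dia_bp = c(95, 80, NA),
    ess = c(12L, 11L, 5L),
    hypertension = c(TRUE, FALSE, NA),
    snoring = c(TRUE, TRUE, FALSE),
    tiredness = c(TRUE, TRUE, FALSE),
    observed_apnea = c(TRUE, FALSE, FALSE),
    ahi = c(45, 28, 4)
  )
}

write_temp_cohort <- function(data, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  sasscreen::write_cohort(data, path)
  path
}

random_cohort <- function(n, seed = NULL) {
  draw <- function() {
    tibble::tibble(
      id = sprintf("r%04d", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = round(runif(n, 20, 85), 1),
      bmi = round(runif(n, 16, 55), 2),
      neck_cm = round(runif(n, 28, 55), 1),
      sys_bp = round(runif(n, 90, 200)),
      dia_bp = ifelse(runif(n) < 0.1, NA, round(runif(n, 55, 120))),
      ess = sample(0:24, n, replace = TRUE),
      hypertension = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
      snoring = sample(c(TRUE, FALSE), n, replace = TRUE),
      tiredness = sample(c(TRUE, FALSE), n, replace = TRUE),
      observed_apnea = sample(c(TRUE, FALSE), n, replace = TRUE),
      ahi = ifelse(runif(n) < 0.05, NA, round(runif(n, 0, 120), 1))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Exhaustive Mann-Whitney pair counting: the independent AUC oracle.
auc_pair_oracle <- function(score, disease) {
  x <- score[disease]
  y <- score[!disease]
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}

# Two-class score/label sample with ties, for ROC property tests.
random_scored_labels <- function(n_max = 200) {
  repeat {
    n <- sample(4:n_max, 1)
    score <- round(runif(n, 0, 10), 1) # one decimal forces ties
    disease <- runif(n) < runif(1, 0.2, 0.8)
    if (any(disease) && !all(disease)) {
      return(list(score = score, disease = disease))
    }
  }
}
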