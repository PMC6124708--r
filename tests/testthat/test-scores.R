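test_that("the SAS score matches direct arithmetic on reference patients", {
  # male, BMI 39, NC 46, SysBP 140, ESS 8: 39/30 + 46/43 + 140/140 + 8/11
  res <- score_sas(worked_example_patient())
  expect_equal(res$sas_score, 39 / 30 + 46 / 43 + 1 + 8 / 11, tolerance = 1e-12)
  expect_equal(res$sas_score, 4.0970, tolerance = 1e-3)
  expect_equal(as.character(res$sas_band), "High")

  # every measurement at its reference value gives exactly 1 per component
  ref <- score_sas(tibble::tibble(sex = "female", bmi = 30, neck_cm = 40,
                                  sys_bp = 140, ess = 11))
  expect_identical(ref$sas_score, 4)
  expect_equal(as.character(ref$sas_band), "High")

  half <- score_sas(tibble::tibble(sex = "female", bmi = 15, neck_cm = 20,
                                   sys_bp = 70, ess = 0))
  expect_equal(half$sas_score, 1.5)
  expect_equal(as.character(half$sas_band), "Low")
})

test_that("missing required measurements are an error, never imputed", {
  p <- worked_example_patient()
  p$ess <- NA_integer_
  expect_error(score_sas(p), "ess", class = "sasscreen_missing_field_error")
  expect_error(score_sas(dplyr::select(worked_example_patient(), -neck_cm)),
               "neck_cm", class = "sasscreen_missing_field_error")
  kept <- score_sas(p, na_action = "keep")
  expect_true(is.na(kept$sas_score))
})

test_that("risk bands partition scores with left-closed boundaries at 3, 3.5, 4, 5", {
  expect_equal(as.character(sas_risk_band(c(2.99, 3, 3.49, 3.5, 3.99, 4, 4.99, 5, 6.2))),
               c("Low", "Mild", "Mild", "Moderate", "Moderate", "High", "High",
                 "Very high", "Very high"))
  # every finite score maps to exactly one band
  grid <- seq(0, 10, by = 0.01)
  bands <- sas_risk_band(grid)
  expect_false(anyNA(bands))
  expect_error(sas_risk_band(Inf), class = "sasscreen_degenerate_error")
  expect_error(sas_risk_band(NA_real_), class = "sasscreen_degenerate_error")
})

test_that("score is additive, linear per component, and sex-symmetric up to the neck reference", {
  withr::with_seed(42, {
    for (i in 1:50) {
      rec <- tibble::tibble(
        sex = sample(c("male", "female"), 1),
        bmi = runif(1, 15, 60), neck_cm = runif(1, 28, 55),
        sys_bp = runif(1, 85, 210), ess = sample(0:24, 1)
      )
      res <- score_sas(rec)
      expect_equal(res$sas_score,
                   res$sub_bmi + res$sub_nc + res$sub_bp + res$sub_ess,
                   tolerance = 1e-12)
      expect_true(all(c(res$sub_bmi, res$sub_nc, res$sub_bp) > 0))

      # doubling one input doubles its sub-score and shifts the total by it
      dbl <- score_sas(dplyr::mutate(rec, bmi = bmi * 2))
      expect_equal(dbl$sub_bmi, 2 * res$sub_bmi, tolerance = 1e-12)
      expect_equal(dbl$sas_score - res$sas_score, res$sub_bmi, tolerance = 1e-12)

      # male and female differ only through the neck denominator
      m <- score_sas(dplyr::mutate(rec, sex = "male"))
      f <- score_sas(dplyr::mutate(rec, sex = "female"))
      expect_equal(f$sas_score - m$sas_score,
                   rec$neck_cm / 40 - rec$neck_cm / 43, tolerance = 1e-12)
    }
  })
})

test_that("STOP-Bang counts one point per satisfied item with positivity at 3", {
  none <- tibble::tibble(sex = "female", age = 40, bmi = 24, neck_cm = 36,
                         hypertension = FALSE, snoring = FALSE,
                         tiredness = FALSE, observed_apnea = FALSE)
  expect_equal(score_stop_bang(none)$stop_bang, 0L)
  expect_false(score_stop_bang(none)$stop_bang_positive)

  all8 <- tibble::tibble(sex = "male", age = 60, bmi = 36, neck_cm = 44,
                         hypertension = TRUE, snoring = TRUE,
                         tiredness = TRUE, observed_apnea = TRUE)
  expect_equal(score_stop_bang(all8)$stop_bang, 8L)
  expect_true(score_stop_bang(all8)$stop_bang_positive)

  # item-by-item: BMI > 35, NC > 41 (female), snoring, tiredness -> 4
  four <- tibble::tibble(sex = "female", age = 45, bmi = 36, neck_cm = 42,
                         hypertension = FALSE, snoring = TRUE,
                         tiredness = TRUE, observed_apnea = FALSE)
  expect_equal(score_stop_bang(four)$stop_bang, 4L)
  expect_true(score_stop_bang(four)$stop_bang_positive)

  # thresholds are strict: values exactly at them score nothing
  at <- tibble::tibble(sex = "female", age = 50, bmi = 35, neck_cm = 41,
                       hypertension = FALSE, snoring = FALSE,
                       tiredness = FALSE, observed_apnea = FALSE)
  expect_equal(score_stop_bang(at)$stop_bang, 0L)
})

test_that("STOP-Bang symptom fallbacks follow the configured precedence", {
  p <- tibble::tibble(sex = "male", age = 60, bmi = 36, neck_cm = 44,
                      sys_bp = 150, dia_bp = 95, ess = 14L,
                      hypertension = NA, snoring = TRUE,
                      tiredness = NA, observed_apnea = FALSE)
  # unresolved tiredness is an error naming the item
  expect_error(score_stop_bang(p), "tiredness",
               class = "sasscreen_missing_field_error")
  # opt-in ESS >= 11 fallback resolves it (and is logged)
  cfg <- comparator_config(tiredness_from_ess = TRUE)
  expect_message(res <- score_stop_bang(p, cfg), "ESS")
  expect_equal(res$stop_bang, 7L) # hypertension derived from 150/95 mmHg
  # a recorded hypertension flag wins over the blood-pressure rule
  p2 <- dplyr::mutate(p, hypertension = FALSE, tiredness = TRUE)
  expect_equal(score_stop_bang(p2)$stop_bang, 6L)
  # with the fallback disabled, unknown hypertension is an error
  p3 <- dplyr::mutate(p, tiredness = TRUE)
  expect_error(score_stop_bang(p3, comparator_config(hypertension_from_bp = FALSE)),
               "hypertension", class = "sasscreen_missing_field_error")
})

test_that("NoSAS awards its point scheme over the 0-17 range with positivity at 8", {
  maxed <- tibble::tibble(sex = "male", age = 56, bmi = 31, neck_cm = 41,
                          snoring = TRUE)
  res <- score_nosas(maxed)
  expect_equal(res$nosas, 17L)
  expect_true(res$nosas_positive)

  zero <- tibble::tibble(sex = "female", age = 30, bmi = 22, neck_cm = 35,
                         snoring = FALSE)
  expect_equal(score_nosas(zero)$nosas, 0L)
  expect_false(score_nosas(zero)$nosas_positive)

  # two-band BMI scheme: 2 (male) + 4 (age) + 3 (BMI 25-30) + 0 (NC) + 2 (snoring)
  mid <- tibble::tibble(sex = "male", age = 60, bmi = 27, neck_cm = 39,
                        snoring = TRUE)
  expect_equal(score_nosas(mid)$nosas, 11L)
  expect_true(score_nosas(mid)$nosas_positive)
  # single-band mode drops the mid-BMI points
  one_band <- comparator_config(nosas_bmi_two_band = FALSE)
  expect_equal(score_nosas(mid, one_band)$nosas, 8L)

  # NoSAS comparisons are inclusive (>=): exactly-at-threshold scores count
  at <- tibble::tibble(sex = "female", age = 55, bmi = 30, neck_cm = 40,
                       snoring = FALSE)
  expect_equal(score_nosas(at)$nosas, 4L + 5L + 4L)

  expect_error(score_nosas(dplyr::select(maxed, -snoring)), "snoring",
               class = "sasscreen_missing_field_error")
})

test_that("the blood-pressure hypertension rule uses 140/90 inclusive thresholds", {
  expect_true(hypertension_from_bp(140, 80))
  expect_true(hypertension_from_bp(120, 90))
  expect_false(hypertension_from_bp(139, 89))
  expect_error(hypertension_from_bp(140, NA),
               class = "sasscreen_missing_field_error")
  expect_error(hypertension_from_bp(-10, 80), class = "sasscreen_validation_error")
})

test_that("comparator configuration rejects non-positive thresholds", {
  expect_error(comparator_config(stop_bang_age_gt = 0),
               class = "sasscreen_config_error")
  expect_error(comparator_config(nosas_age_points = -1),
               class = "sasscreen_config_error")
})

test_that("scores over a large generated cohort mostly fall in (2, 7)", {
  cohort <- suppressMessages(generate_cohort(westro_cohort_spec(n = 10000, seed = 31)))
  s <- score_sas(cohort)$sas_score
  expect_gte(mean(s > 2 & s < 7), 0.99)
})
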