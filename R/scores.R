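# Reference denominators of the simplified SAS score: each measurement is
# standardised by a fixed clinically conventional value, and the four
# standardised components are summed. Neck circumference uses a sex-specific
# reference (40 cm women, 43 cm men).
SAS_REFERENCE <- c(bmi = 30, nc_female = 40, nc_male = 43, sys_bp = 140, ess = 11)
SAS_BAND_CUTS <- c(3, 3.5, 4, 5)
SAS_BAND_LEVELS <- c("Low", "Mild", "Moderate", "High", "Very high")

#' Map SAS score values to risk bands
#'
#' Scores partition into five ordered risk bands with left-closed boundaries
#' at 3, 3.5, 4 and 5: Low below 3, Mild in \[3, 3.5), Moderate in
#' \[3.5, 4), High in \[4, 5) and Very high at 5 or above.
#'
#' @param score Numeric vector of SAS score values; must be finite.
#' @return An ordered factor with levels Low < Mild < Moderate < High <
#'   Very high.
#' @export
#' @examples
#' sas_risk_band(c(2.99, 3, 3.5, 4.2, 5))
sas_risk_band <- function(score) {
  if (!is.numeric(score)) stop_degenerate("score must be numeric")
  if (any(!is.finite(score))) {
    stop_degenerate("score must be finite to be assigned a risk band")
  }
  cut(score, breaks = c(-Inf, SAS_BAND_CUTS, Inf), labels = SAS_BAND_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

sas_subscores_at <- function(sex, bmi, neck_cm, sys_bp, ess) {
  nc_ref <- ifelse(sex == "female", SAS_REFERENCE[["nc_female"]],
                   SAS_REFERENCE[["nc_male"]])
  tibble(
    sub_bmi = bmi / SAS_REFERENCE[["bmi"]],
    sub_nc = neck_cm / nc_ref,
    sub_bp = sys_bp / SAS_REFERENCE[["sys_bp"]],
    sub_ess = ess / SAS_REFERENCE[["ess"]]
  )
}

#' Compute the SAS score
#'
#' The SAS score is the sum of four standardised components:
#' `bmi / 30 + neck_cm / 40 (women) or 43 (men) + sys_bp / 140 + ess / 11`.
#' It is a dimensionless decimal value, in practice within roughly (2, 7),
#' rising with obstructive-sleep-apnea severity; [sas_risk_band()] maps it
#' to a five-level risk band.
#'
#' @param data A data frame with columns `sex` (`"male"`/`"female"`), `bmi`
#'   (kg/m2), `neck_cm` (cm), `sys_bp` (mmHg) and `ess` (0-24). Additional
#'   columns are carried through.
#' @param na_action `"error"` (default) aborts naming the first missing
#'   required field; `"keep"` leaves `NA` scores for incomplete rows so
#'   callers can report per-row rejections.
#' @return The input as a tibble with columns `sub_bmi`, `sub_nc`, `sub_bp`,
#'   `sub_ess`, `sas_score` and `sas_band` appended.
#' @export
#' @examples
#' library(tibble)
#' tibble(sex = "male", bmi = 39, neck_cm = 46, sys_bp = 140, ess = 8) |>
#'   score_sas()
score_sas <- function(data, na_action = c("error", "keep")) {
  na_action <- match.arg(na_action)
  data <- as_tibble(data)
  required <- c("sex", "bmi", "neck_cm", "sys_bp", "ess")
  for (f in required) {
    if (!f %in% names(data)) stop_missing_field(f, "needed for the SAS score")
    if (na_action == "error" && anyNA(data[[f]])) {
      stop_missing_field(f, sprintf("missing in row %d; the SAS score is never imputed",
                                    which(is.na(data[[f]]))[1]))
    }
  }
  bad_sex <- !is.na(data$sex) & !data$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop_validation(sprintf("sex must be 'male' or 'female' (row %d)",
                            which(bad_sex)[1]))
  }
  subs <- sas_subscores_at(data$sex, data$bmi, data$neck_cm, data$sys_bp, data$ess)
  value <- subs$sub_bmi + subs$sub_nc + subs$sub_bp + subs$sub_ess
  out <- dplyr::bind_cols(data, subs)
  out$sas_score <- value
  out$sas_band <- SAS_BAND_LEVELS[
    findInterval(value, c(-Inf, SAS_BAND_CUTS)) ]
  out$sas_band[!is.finite(value)] <- NA_character_
  out$sas_band <- factor(out$sas_band, levels = SAS_BAND_LEVELS, ordered = TRUE)
  out
}

#' Comparator questionnaire configuration
#'
#' Thresholds and point schemes for the STOP-Bang and NoSAS comparator
#' scores. Defaults follow the published instruments: STOP-Bang items use
#' strict comparisons (age > 50 y, BMI > 35 kg/m2, neck > 41 cm women /
#' 43 cm men, positive at >= 3 of 8 points); NoSAS awards 4 points for neck
#' >= 40 cm, 3 points for 25 <= BMI < 30 and 5 for BMI >= 30 (two-band
#' scheme; set `nosas_bmi_two_band = FALSE` for a single 5-point band at
#' BMI >= 30), 2 for snoring, 4 for age >= 55 y and 2 for male sex,
#' positive at >= 8 of 17.
#'
#' @param stop_bang_age_gt,stop_bang_bmi_gt,stop_bang_nc_gt_female,stop_bang_nc_gt_male
#'   STOP-Bang item thresholds (strict `>`).
#' @param stop_bang_positive_at STOP-Bang positivity cut-off (`>=`).
#' @param nosas_nc_ge,nosas_nc_points,nosas_bmi_mid_points,nosas_bmi_high_points,nosas_snoring_points,nosas_age_ge,nosas_age_points,nosas_male_points
#'   NoSAS thresholds (`>=`) and point values.
#' @param nosas_positive_at NoSAS positivity cut-off (`>=`).
#' @param nosas_bmi_two_band Use the two-band BMI scheme (default `TRUE`).
#' @param tiredness_from_ess If `TRUE`, a missing STOP-Bang tiredness flag
#'   falls back to `ess >= 11` (the conventional sleepiness threshold);
#'   off by default so missing answers surface as errors.
#' @param hypertension_from_bp If `TRUE` (default), a missing hypertension
#'   flag falls back to the blood-pressure rule of
#'   [hypertension_from_bp()] when both pressures are present. A recorded
#'   flag always wins.
#' @return A list of class `comparator_config`.
#' @export
comparator_config <- function(stop_bang_age_gt = 50,
                              stop_bang_bmi_gt = 35,
                              stop_bang_nc_gt_female = 41,
                              stop_bang_nc_gt_male = 43,
                              stop_bang_positive_at = 3,
                              nosas_nc_ge = 40,
                              nosas_nc_points = 4,
                              nosas_bmi_mid_points = 3,
                              nosas_bmi_high_points = 5,
                              nosas_snoring_points = 2,
                              nosas_age_ge = 55,
                              nosas_age_points = 4,
                              nosas_male_points = 2,
                              nosas_positive_at = 8,
                              nosas_bmi_two_band = TRUE,
                              tiredness_from_ess = FALSE,
                              hypertension_from_bp = TRUE) {
  cfg <- as.list(environment())
  thresholds <- c(cfg$stop_bang_age_gt, cfg$stop_bang_bmi_gt,
                  cfg$stop_bang_nc_gt_female, cfg$stop_bang_nc_gt_male,
                  cfg$nosas_nc_ge, cfg$nosas_age_ge)
  points <- c(cfg$nosas_nc_points, cfg$nosas_bmi_mid_points,
              cfg$nosas_bmi_high_points, cfg$nosas_snoring_points,
              cfg$nosas_age_points, cfg$nosas_male_points)
  if (any(thresholds <= 0)) stop_config("comparator thresholds must be strictly positive")
  if (any(points < 0)) stop_config("comparator point values must be non-negative")
  structure(cfg, class = "comparator_config")
}

#' Hypertension from blood-pressure readings
#'
#' A patient is flagged hypertensive when systolic pressure is at least
#' 140 mmHg or diastolic pressure is at least 90 mmHg.
#'
#' @param sys_bp,dia_bp Systolic and diastolic pressure in mmHg; both must
#'   be present and positive.
#' @return Logical vector.
#' @export
#' @examples
#' hypertension_from_bp(c(140, 120, 139), c(80, 90, 89))
hypertension_from_bp <- function(sys_bp, dia_bp) {
  if (missing(sys_bp) || missing(dia_bp)) {
    stop_missing_field(if (missing(sys_bp)) "sys_bp" else "dia_bp",
                       "both pressures are needed for the blood-pressure rule")
  }
  if (anyNA(sys_bp) || anyNA(dia_bp)) {
    stop_missing_field(if (anyNA(sys_bp)) "sys_bp" else "dia_bp",
                       "both pressures are needed for the blood-pressure rule")
  }
  if (any(sys_bp <= 0) || any(dia_bp <= 0)) {
    stop_validation("blood pressures must be positive")
  }
  sys_bp >= 140 | dia_bp >= 90
}

# Resolve the tristate hypertension flag for the STOP-Bang pressure item:
# a recorded flag wins; the BP rule fills in only when the flag is unknown
# and both pressures exist (and the fallback is enabled).
resolve_hypertension <- function(data, config) {
  flag <- if ("hypertension" %in% names(data)) data$hypertension else rep(NA, nrow(data))
  if (isTRUE(config$hypertension_from_bp) &&
      all(c("sys_bp", "dia_bp") %in% names(data))) {
    derivable <- is.na(flag) & !is.na(data$sys_bp) & !is.na(data$dia_bp) &
      data$sys_bp > 0 & data$dia_bp > 0
    flag[derivable] <- data$sys_bp[derivable] >= 140 | data$dia_bp[derivable] >= 90
  }
  flag
}

require_cols <- function(data, cols, score_name) {
  for (f in cols) {
    if (!f %in% names(data)) {
      stop_missing_field(f, sprintf("needed for the %s score", score_name))
    }
  }
}

require_complete <- function(x, field, score_name) {
  if (anyNA(x)) {
    stop_missing_field(field, sprintf("unresolved in row %d for the %s score",
                                      which(is.na(x))[1], score_name))
  }
  x
}

#' Compute the STOP-Bang score
#'
#' Eight one-point items: snoring, tiredness, observed apnea, hypertension
#' (the recorded flag, or the blood-pressure rule when the flag is unknown),
#' BMI > 35 kg/m2, age > 50 y, neck circumference > 41 cm (women) / 43 cm
#' (men), and male sex. Positive at 3 or more points.
#'
#' @inheritParams score_sas
#' @param config A [comparator_config()].
#' @return The input as a tibble with integer `stop_bang` (0-8) and logical
#'   `stop_bang_positive` appended.
#' @export
score_stop_bang <- function(data, config = comparator_config()) {
  data <- as_tibble(data)
  require_cols(data, c("sex", "age", "bmi", "neck_cm"), "STOP-Bang")
  for (f in c("sex", "age", "bmi", "neck_cm")) {
    require_complete(data[[f]], f, "STOP-Bang")
  }
  hyp <- require_complete(resolve_hypertension(data, config), "hypertension", "STOP-Bang")
  snore <- require_complete(
    if ("snoring" %in% names(data)) data$snoring else rep(NA, nrow(data)),
    "snoring", "STOP-Bang")
  tired <- if ("tiredness" %in% names(data)) data$tiredness else rep(NA, nrow(data))
  if (isTRUE(config$tiredness_from_ess) && "ess" %in% names(data)) {
    fallback <- is.na(tired) & !is.na(data$ess)
    if (any(fallback)) {
      inform(sprintf("tiredness derived from ESS >= 11 for %d row(s)", sum(fallback)))
      tired[fallback] <- data$ess[fallback] >= 11
    }
  }
  tired <- require_complete(tired, "tiredness", "STOP-Bang")
  apnea <- require_complete(
    if ("observed_apnea" %in% names(data)) data$observed_apnea else rep(NA, nrow(data)),
    "observed_apnea", "STOP-Bang")

  nc_thr <- ifelse(data$sex == "female", config$stop_bang_nc_gt_female,
                   config$stop_bang_nc_gt_male)
  score <- as.integer(snore) + as.integer(tired) + as.integer(apnea) +
    as.integer(hyp) +
    as.integer(data$bmi > config$stop_bang_bmi_gt) +
    as.integer(data$age > config$stop_bang_age_gt) +
    as.integer(data$neck_cm > nc_thr) +
    as.integer(data$sex == "male")
  data$stop_bang <- score
  data$stop_bang_positive <- score >= config$stop_bang_positive_at
  data
}

#' Compute the NoSAS score
#'
#' Point scheme: neck circumference >= 40 cm (4 points), BMI (3 points for
#' 25 <= BMI < 30 and 5 for BMI >= 30 under the default two-band scheme, or
#' a single 5-point band at BMI >= 30), snoring (2), age >= 55 y (4) and
#' male sex (2); the total ranges 0-17 and is positive at 8 or more.
#'
#' @inheritParams score_stop_bang
#' @return The input as a tibble with integer `nosas` (0-17) and logical
#'   `nosas_positive` appended.
#' @export
score_nosas <- function(data, config = comparator_config()) {
  data <- as_tibble(data)
  require_cols(data, c("sex", "age", "bmi", "neck_cm", "snoring"), "NoSAS")
  for (f in c("sex", "age", "bmi", "neck_cm", "snoring")) {
    require_complete(data[[f]], f, "NoSAS")
  }
  bmi_pts <- if (isTRUE(config$nosas_bmi_two_band)) {
    ifelse(data$bmi >= 30, config$nosas_bmi_high_points,
           ifelse(data$bmi >= 25, config$nosas_bmi_mid_points, 0))
  } else {
    ifelse(data$bmi >= 30, config$nosas_bmi_high_points, 0)
  }
  score <- config$nosas_nc_points * (data$neck_cm >= config$nosas_nc_ge) +
    bmi_pts +
    config$nosas_snoring_points * data$snoring +
    config$nosas_age_points * (data$age >= config$nosas_age_ge) +
    config$nosas_male_points * (data$sex == "male")
  data$nosas <- as.integer(score)
  data$nosas_positive <- data$nosas >= config$nosas_positive_at
  data
}
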