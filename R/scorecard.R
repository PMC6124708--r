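#' Sub-score lookup table for one SAS component
#'
#' Tabulates one standardised component of the SAS score over a grid of raw
#' measurement values: the sub-score is the measurement divided by its fixed
#' reference (BMI 30 kg/m2, neck 40 cm women / 43 cm men, systolic pressure
#' 140 mmHg, Epworth score 11), so the table is linear and equals exactly 1
#' at the reference value. These tables are the chart form of the score for
#' offline use.
#'
#' @param component One of `"bmi"`, `"nc_female"`, `"nc_male"`, `"bp"`,
#'   `"ess"`.
#' @param grid Numeric vector of measurement values (non-negative, finite).
#' @return A tibble with columns `input` and `subscore`, of class
#'   `sas_subscore_table`.
#' @export
#' @examples
#' subscore_table("bmi", seq(15, 60, by = 5))
subscore_table <- function(component = c("bmi", "nc_female", "nc_male", "bp", "ess"),
                           grid) {
  component <- match.arg(component)
  if (missing(grid) || length(grid) == 0) {
    stop_empty("sub-score grid must be non-empty")
  }
  if (!is.numeric(grid) || any(!is.finite(grid)) || any(grid < 0)) {
    stop_validation("sub-score grid values must be finite and non-negative")
  }
  denom <- switch(component,
    bmi = SAS_REFERENCE[["bmi"]],
    nc_female = SAS_REFERENCE[["nc_female"]],
    nc_male = SAS_REFERENCE[["nc_male"]],
    bp = SAS_REFERENCE[["sys_bp"]],
    ess = SAS_REFERENCE[["ess"]]
  )
  out <- tibble(input = sort(grid), subscore = sort(grid) / denom)
  attr(out, "component") <- component
  attr(out, "reference") <- denom
  class(out) <- c("sas_subscore_table", class(out))
  out
}

check_bins <- function(bins, what) {
  if (!is.numeric(bins) || length(bins) < 2 || any(!is.finite(bins))) {
    stop_config(sprintf("%s bins must be a numeric vector of at least 2 finite breaks", what))
  }
  if (any(diff(bins) <= 0)) {
    stop_config(sprintf("%s bins must be strictly increasing (contiguous, non-overlapping)", what))
  }
  bins
}

#' Severity scorecard over binned measurements
#'
#' Builds the printable scorecard approximation of the SAS score: each of
#' the four measurements is binned, every bin combination becomes a cell,
#' and the cell holds the score and risk band evaluated at a representative
#' point of each bin (the midpoint by default). Because each component is
#' increasing in its measurement, cell scores are non-decreasing along any
#' single bin axis.
#'
#' @param bmi_bins,nc_bins,bp_bins,ess_bins Strictly increasing numeric
#'   break vectors (length k+1 defines k contiguous bins).
#' @param sex `"male"` or `"female"` (selects the neck reference).
#' @param representative `"midpoint"` (default), `"lower"` or `"upper"`:
#'   the point within each bin at which the score is evaluated.
#' @return A tibble of class `sas_scorecard` with one row per cell: the bin
#'   bounds and labels per component, the representative values, `sas_score`
#'   and `sas_band`.
#' @export
#' @examples
#' scorecard_grid(c(20, 30, 40), c(35, 40, 45), c(110, 140, 170), c(0, 11, 24),
#'                sex = "female")
scorecard_grid <- function(bmi_bins, nc_bins, bp_bins, ess_bins,
                           sex = c("female", "male"),
                           representative = c("midpoint", "lower", "upper")) {
  sex <- match.arg(sex)
  representative <- match.arg(representative)
  check_bins(bmi_bins, "bmi")
  check_bins(nc_bins, "nc")
  check_bins(bp_bins, "bp")
  check_bins(ess_bins, "ess")

  rep_point <- function(lo, hi) {
    switch(representative, midpoint = (lo + hi) / 2, lower = lo, upper = hi)
  }
  bins_tbl <- function(breaks, prefix) {
    lo <- utils::head(breaks, -1)
    hi <- utils::tail(breaks, -1)
    tibble(
      "{prefix}_lo" := lo, "{prefix}_hi" := hi,
      "{prefix}_bin" := sprintf("[%g, %g)", lo, hi),
      "{prefix}_rep" := rep_point(lo, hi)
    )
  }
  cells <- tidyr::expand_grid(
    bins_tbl(bmi_bins, "bmi"),
    bins_tbl(nc_bins, "nc"),
    bins_tbl(bp_bins, "bp"),
    bins_tbl(ess_bins, "ess")
  )
  scored <- score_sas(tibble(
    sex = sex,
    bmi = cells$bmi_rep, neck_cm = cells$nc_rep,
    sys_bp = cells$bp_rep, ess = cells$ess_rep
  ))
  cells$sas_score <- scored$sas_score
  cells$sas_band <- scored$sas_band
  attr(cells, "sex") <- sex
  attr(cells, "representative") <- representative
  class(cells) <- c("sas_scorecard", class(cells))
  cells
}
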