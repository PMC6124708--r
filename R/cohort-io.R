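# Canonical per-patient fields. Continuous measurements are doubles, the
# Epworth score is a bounded integer, symptom flags are tristate logicals
# (TRUE / FALSE / NA = unknown) and AHI is the optional reference standard.
COHORT_FIELDS <- c(
  "id", "sex", "age", "bmi", "neck_cm", "sys_bp", "dia_bp", "ess",
  "hypertension", "snoring", "tiredness", "observed_apnea", "ahi"
)
CONTINUOUS_FIELDS <- c("age", "bmi", "neck_cm", "sys_bp", "dia_bp", "ahi")
FLAG_FIELDS <- c("hypertension", "snoring", "tiredness", "observed_apnea")
REQUIRED_MAPPED <- c("sex", "bmi", "neck_cm", "sys_bp", "ess")

parse_sex <- function(x, male_code = "1") {
  x_chr <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(x_chr))
  out[x_chr %in% c("m", "male")] <- "male"
  out[x_chr %in% c("f", "female")] <- "female"
  numeric_tokens <- x_chr %in% c("0", "1")
  out[numeric_tokens] <- ifelse(x_chr[numeric_tokens] == male_code, "male", "female")
  out[is.na(x_chr) | x_chr == ""] <- NA_character_
  bad <- !is.na(x_chr) & x_chr != "" & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

parse_flag <- function(x) {
  x_chr <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "yes", "y", "true", "t")] <- TRUE
  out[x_chr %in% c("0", "no", "n", "false", "f")] <- FALSE
  bad <- !is.na(x_chr) & x_chr != "" & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

parse_num <- function(x) {
  x_chr <- trimws(as.character(x))
  x_chr[x_chr == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x_chr))
  attr(out, "bad") <- which(!is.na(x_chr) & is.na(out))
  out
}

#' Read a patient cohort from a delimited text file
#'
#' Reads a comma- or tab-delimited cohort table into the package's canonical
#' layout: one row per patient with columns `id`, `sex`, `age`, `bmi`,
#' `neck_cm`, `sys_bp`, `dia_bp`, `ess`, `hypertension`, `snoring`,
#' `tiredness`, `observed_apnea` and `ahi`. Source files rarely use these
#' names, so a column mapping (canonical field -> source column name) is
#' supplied either as a named character vector or as a YAML file. Unmapped
#' source columns are ignored; row order is preserved; empty cells become
#' missing values and are never imputed.
#'
#' @param path Path to a delimited text file.
#' @param mapping Named character vector mapping canonical field names to
#'   source column names, or the path of a YAML file holding that mapping.
#'   `NULL` (default) assumes the file already uses canonical names. Must
#'   cover at least `sex`, `bmi`, `neck_cm`, `sys_bp` and `ess`.
#' @param delim Field delimiter; `NULL` guesses `","` unless the path ends in
#'   `.tsv`/`.txt`, in which case tab is used.
#' @param male_code When sex is coded 0/1, the token meaning male
#'   (default `"1"`).
#' @param strict If `TRUE` (default) any parse or validation problem aborts
#'   with an error naming the row and field; if `FALSE` offending rows are
#'   dropped and returned in the `"problems"` attribute, one row per issue.
#'
#' @return A tibble with the canonical columns, one row per retained data
#'   row. Attributes: `"provenance"` (the source path) and, when
#'   `strict = FALSE`, `"problems"`.
#' @seealso [write_cohort()], [validate_cohort()], [cohort_summary()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,sex,bmi,neck_cm,sys_bp,ess",
#'              "p1,male,39,46,140,8"), f)
#' read_cohort(f)
read_cohort <- function(path, mapping = NULL, delim = NULL,
                        male_code = "1", strict = TRUE) {
  if (!file.exists(path)) {
    stop_validation(sprintf("cohort file not found: %s", path))
  }
  if (is.character(mapping) && length(mapping) == 1 && is.null(names(mapping)) &&
      file.exists(mapping)) {
    mapping <- unlist(yaml::read_yaml(mapping))
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), show_col_types = FALSE, progress = FALSE)

  if (is.null(mapping)) {
    mapping <- intersect(COHORT_FIELDS, names(raw))
    names(mapping) <- mapping
  }
  unknown <- setdiff(names(mapping), COHORT_FIELDS)
  if (length(unknown) > 0) {
    stop_config(sprintf("mapping contains unknown canonical field(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  missing_req <- setdiff(REQUIRED_MAPPED, names(mapping))
  if (length(missing_req) > 0) {
    stop_schema(sprintf("mapping must cover required field(s): %s",
                        paste(missing_req, collapse = ", ")))
  }
  absent <- setdiff(unname(mapping), names(raw))
  if (length(absent) > 0) {
    stop_schema(sprintf("mapped column(s) not present in file: %s",
                        paste(absent, collapse = ", ")))
  }

  n <- nrow(raw)
  cohort <- tibble(.rows = n)
  problems <- list()
  note <- function(rows, field, problem) {
    if (length(rows) > 0) {
      problems[[length(problems) + 1]] <<- tibble(
        row = rows, field = field, problem = problem
      )
    }
  }

  for (field in COHORT_FIELDS) {
    if (!field %in% names(mapping)) {
      cohort[[field]] <- switch(
        field,
        id = sprintf("row%d", seq_len(n)),
        sex = rep(NA_character_, n),
        ess = rep(NA_integer_, n),
        hypertension = , snoring = , tiredness = , observed_apnea = rep(NA, n),
        rep(NA_real_, n)
      )
      next
    }
    src <- raw[[mapping[[field]]]]
    if (field == "id") {
      cohort$id <- as.character(src)
    } else if (field == "sex") {
      val <- parse_sex(src, male_code = male_code)
      note(attr(val, "bad"), "sex", "unrecognised sex token")
      cohort$sex <- as.vector(val)
    } else if (field %in% FLAG_FIELDS) {
      val <- parse_flag(src)
      note(attr(val, "bad"), field, "unrecognised yes/no token")
      cohort[[field]] <- as.vector(val)
    } else {
      val <- parse_num(src)
      note(attr(val, "bad"), field, "unparseable number")
      cohort[[field]] <- as.vector(val)
    }
  }
  if ("ess" %in% names(mapping)) {
    frac <- which(!is.na(cohort$ess) & abs(cohort$ess - round(cohort$ess)) > 1e-9)
    note(frac, "ess", "Epworth score must be a whole number")
    cohort$ess[frac] <- NA_real_
  }

  problems <- dplyr::bind_rows(
    if (length(problems) > 0) dplyr::bind_rows(problems) else tibble(row = integer(), field = character(), problem = character()),
    validate_cohort(cohort)
  )
  problems <- dplyr::arrange(problems, .data$row, .data$field)

  if (nrow(problems) > 0 && strict) {
    shown <- utils::head(problems, 5)
    stop_validation(paste0(
      sprintf("cohort file failed validation (%d problem%s):\n", nrow(problems),
              if (nrow(problems) == 1) "" else "s"),
      paste(sprintf("  row %d, %s: %s", shown$row, shown$field, shown$problem),
            collapse = "\n")
    ), problems = problems)
  }
  if (nrow(problems) > 0) {
    cohort <- cohort[-unique(problems$row), , drop = FALSE]
  }
  attr(cohort, "provenance") <- path
  attr(cohort, "problems") <- problems
  cohort
}

#' Validate a cohort table
#'
#' Checks range and category invariants on an in-memory cohort: positive
#' BMI, neck circumference and systolic pressure, Epworth score within 0-24,
#' non-negative AHI, recognised sex categories and unique patient ids.
#' Missing values are allowed everywhere (they are reported at scoring time,
#' not here).
#'
#' @param data A cohort tibble in canonical layout (see [read_cohort()]).
#' @return A tibble of problems with columns `row`, `field`, `problem`;
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(data) {
  out <- list()
  note <- function(rows, field, problem) {
    if (length(rows) > 0) {
      out[[length(out) + 1]] <<- tibble(row = rows, field = field, problem = problem)
    }
  }
  chk <- function(field, bad_fun, problem) {
    if (field %in% names(data)) {
      v <- data[[field]]
      note(which(!is.na(v) & bad_fun(v)), field, problem)
    }
  }
  chk("bmi", function(v) v <= 0, "bmi must be > 0")
  chk("neck_cm", function(v) v <= 0, "neck_cm must be > 0")
  chk("sys_bp", function(v) v <= 0, "sys_bp must be > 0")
  chk("dia_bp", function(v) v <= 0, "dia_bp must be > 0")
  chk("ess", function(v) v < 0 | v > 24, "ess must lie within the 0-24 bound")
  chk("ahi", function(v) v < 0, "ahi must be >= 0")
  chk("age", function(v) v <= 0, "age must be > 0")
  if ("sex" %in% names(data)) {
    v <- data$sex
    note(which(!is.na(v) & !v %in% c("male", "female")),
         "sex", "sex must be 'male' or 'female'")
  }
  if ("id" %in% names(data)) {
    dup <- which(duplicated(data$id) & !is.na(data$id))
    note(dup, "id", "duplicate patient id")
  }
  if (length(out) == 0) {
    tibble(row = integer(), field = character(), problem = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Write a cohort to a delimited text file
#'
#' Serialises a canonical cohort table as delimited text with full numeric
#' precision, encoding missing values as empty cells so that
#' `read_cohort(write_cohort(x, f))` reproduces every field value exactly.
#'
#' @param data A cohort tibble in canonical layout.
#' @param path Output path; a `.tsv` extension selects tab delimiting.
#' @param delim Field delimiter; `NULL` chooses from the path as in
#'   [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  out <- data[, intersect(COHORT_FIELDS, names(data)), drop = FALSE]
  for (f in FLAG_FIELDS) {
    if (f %in% names(out)) {
      out[[f]] <- ifelse(is.na(out[[f]]), NA_character_,
                         ifelse(out[[f]], "yes", "no"))
    }
  }
  tryCatch(
    readr::write_delim(out, path, delim = delim, na = ""),
    error = function(e) {
      abort(sprintf("cannot write cohort file '%s': %s", path, conditionMessage(e)),
            class = "sasscreen_io_error")
    }
  )
  invisible(path)
}

#' Summarise a cohort
#'
#' Computes per-variable descriptive statistics in the layout customary for
#' a cohort table: mean and sample (n-1) standard deviation for continuous
#' variables, count and percentage for binary ones. Each statistic uses only
#' non-missing values and reports its own denominator. Derived indicator
#' rows (obesity BMI > 30, sleepiness ESS >= 11, AHI >= 30) are included
#' because they are the conventional way such cohorts are described.
#'
#' @param data A cohort tibble in canonical layout, with at least one row.
#' @return A tibble of class `osa_cohort_summary` with columns `variable`,
#'   `type` (`"continuous"` or `"binary"`), `mean`, `sd`, `count`, `percent`
#'   and `n` (non-missing denominator). The total row count is in the
#'   `"n_total"` attribute. Percentages are stored at full precision; the
#'   print method rounds them to one decimal.
#' @export
cohort_summary <- function(data) {
  if (is.null(data) || nrow(data) == 0) {
    stop_empty("cannot summarise an empty cohort")
  }
  cont_row <- function(variable, v) {
    v <- v[!is.na(v)]
    tibble(variable = variable, type = "continuous",
           mean = if (length(v) > 0) mean(v) else NA_real_,
           sd = if (length(v) > 1) sd(v) else NA_real_,
           count = NA_real_, percent = NA_real_, n = length(v))
  }
  bin_row <- function(variable, v) {
    v <- v[!is.na(v)]
    tibble(variable = variable, type = "binary",
           mean = NA_real_, sd = NA_real_,
           count = sum(v), percent = if (length(v) > 0) 100 * mean(v) else NA_real_,
           n = length(v))
  }
  gv <- function(f) if (f %in% names(data)) data[[f]] else rep(NA_real_, nrow(data))
  rows <- dplyr::bind_rows(
    bin_row("male", gv("sex") == "male"),
    cont_row("age", gv("age")),
    cont_row("bmi", gv("bmi")),
    bin_row("obesity_bmi_gt_30", gv("bmi") > 30),
    cont_row("neck_cm", gv("neck_cm")),
    cont_row("sys_bp", gv("sys_bp")),
    cont_row("dia_bp", gv("dia_bp")),
    bin_row("hypertension", gv("hypertension")),
    bin_row("snoring", gv("snoring")),
    bin_row("tiredness", gv("tiredness")),
    bin_row("observed_apnea", gv("observed_apnea")),
    cont_row("ess", gv("ess")),
    bin_row("sleepiness_ess_ge_11", gv("ess") >= 11),
    cont_row("ahi", gv("ahi")),
    bin_row("ahi_ge_30", gv("ahi") >= 30)
  )
  attr(rows, "n_total") <- nrow(data)
  class(rows) <- c("osa_cohort_summary", class(rows))
  rows
}

#' @export
print.osa_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (N = %d)\n", attr(x, "n_total")))
  for (i in seq_len(nrow(x))) {
    if (x$type[i] == "continuous") {
      if (x$n[i] > 0) {
        cat(sprintf("  %-22s %8.2f +/- %.2f  (n = %d)\n",
                    x$variable[i], x$mean[i], x$sd[i], x$n[i]))
      }
    } else if (x$n[i] > 0) {
      cat(sprintf("  %-22s %5d (%.1f%%)  (n = %d)\n",
                  x$variable[i], x$count[i], x$percent[i], x$n[i]))
    }
  }
  invisible(x)
}
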