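# Default plausibility bounds for generated measurements; values falling
# outside are clipped and the events counted in the generator report.
DEFAULT_CLIP <- list(
  age = c(18, 95), bmi = c(14, 70), neck_cm = c(25, 60),
  sys_bp = c(80, 240), dia_bp = c(40, 160), ess = c(0, 24), ahi = c(0, 150)
)

#' Specification of a synthetic patient cohort
#'
#' Defines the generative model behind [generate_cohort()]: each patient
#' carries a latent severity factor `z ~ N(0, 1)`; every continuous
#' measurement is `mean + SD * (loading * z + sqrt(1 - loading^2) * e)`
#' with an independent standard-normal residual `e`, so the stated marginal
#' mean and SD are preserved while all variables co-vary through severity.
#' Binary symptoms follow logistic models in `z` whose intercepts are
#' solved so the stated marginal rates hold. AHI is a monotone function of
#' its own severity index: linear (`ahi_family = "normal"`) or a
#' shifted-gamma quantile transform (`ahi_family = "gamma"`) that matches
#' the stated mean and SD *and* the target prevalence of AHI >= 30 exactly,
#' reproducing the right skew of real AHI distributions.
#'
#' @param n Number of patients (>= 0).
#' @param seed Master integer seed; all randomness derives from it.
#' @param male_frac Proportion of male patients.
#' @param marginals Named list of `c(mean, sd)` for `age`, `bmi`,
#'   `neck_cm`, `sys_bp`, `ess`, `ahi`.
#' @param loadings Named vector of severity-factor loadings in \[-1, 1\]
#'   for the same variables.
#' @param symptom_rates Named marginal rates for `snoring`, `tiredness`,
#'   `observed_apnea`.
#' @param symptom_slope Logistic slope of each symptom on `z`.
#' @param target_prevalence Target proportion with AHI >= 30.
#' @param ahi_family `"gamma"` (skewed, prevalence-exact) or `"normal"`.
#' @param male_nc_shift Additive neck-circumference shift for men (cm),
#'   applied about the sex-mix mean so the overall marginal is unchanged.
#' @param dia_intercept,dia_slope,dia_sd Diastolic pressure model
#'   `dia = intercept + slope * sys + N(0, sd)`; the defaults make the
#'   blood-pressure hypertension rule flag about 67.5% of patients.
#' @param clip Named list of `c(lo, hi)` plausibility bounds.
#' @return A list of class `cohort_spec`.
#' @seealso [westro_cohort_spec()] for the sleep-laboratory defaults.
#' @export
cohort_spec <- function(n = 1000,
                        seed = 1L,
                        male_frac = 0.5,
                        marginals = list(age = c(50, 15), bmi = c(28, 6),
                                         neck_cm = c(40, 5), sys_bp = c(130, 18),
                                         ess = c(9, 5), ahi = c(25, 20)),
                        loadings = c(age = 0.2, bmi = 0.5, neck_cm = 0.5,
                                     sys_bp = 0.3, ess = 0.5, ahi = 0.8),
                        symptom_rates = c(snoring = 0.6, tiredness = 0.5,
                                          observed_apnea = 0.4),
                        symptom_slope = 0.8,
                        target_prevalence = 0.4,
                        ahi_family = c("normal", "gamma"),
                        male_nc_shift = 1.5,
                        dia_intercept = 14.4, dia_slope = 0.6, dia_sd = 8,
                        clip = DEFAULT_CLIP) {
  ahi_family <- match.arg(ahi_family)
  spec <- list(
    n = n, seed = as.integer(seed), male_frac = male_frac,
    marginals = marginals, loadings = loadings,
    symptom_rates = symptom_rates, symptom_slope = symptom_slope,
    target_prevalence = target_prevalence, ahi_family = ahi_family,
    male_nc_shift = male_nc_shift,
    dia_intercept = dia_intercept, dia_slope = dia_slope, dia_sd = dia_sd,
    clip = clip
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  vars <- c("age", "bmi", "neck_cm", "sys_bp", "ess", "ahi")
  if (is.na(spec$n) || spec$n < 0) stop_config("spec n must be >= 0")
  missing_m <- setdiff(vars, names(spec$marginals))
  if (length(missing_m) > 0) {
    stop_config(sprintf("marginals missing for: %s", paste(missing_m, collapse = ", ")))
  }
  sds <- vapply(spec$marginals[vars], `[`, numeric(1), 2)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop_config("all marginal SDs must be positive")
  }
  missing_l <- setdiff(vars, names(spec$loadings))
  if (length(missing_l) > 0) {
    stop_config(sprintf("loadings missing for: %s", paste(missing_l, collapse = ", ")))
  }
  if (any(abs(spec$loadings[vars]) > 1)) {
    stop_config("loading magnitudes must not exceed 1")
  }
  props <- c(spec$male_frac, spec$target_prevalence, spec$symptom_rates)
  if (any(props < 0 | props > 1)) {
    stop_config("male_frac, target_prevalence and symptom rates must lie in [0, 1]")
  }
  invisible(spec)
}

#' Sleep-laboratory referral cohort defaults
#'
#' A [cohort_spec()] reproducing the descriptive statistics of a large
#' Western-Romanian sleep-laboratory referral cohort (N = 2595): age
#' 52.2 +/- 13.25 y, BMI 33.73 +/- 7.11 kg/m2, neck 43.15 +/- 5.25 cm,
#' Epworth score 11.16 +/- 5.40, AHI 43.54 +/- 26.57 events/h, 69.2% male,
#' 78.0% snorers, and 64.4% with AHI >= 30. Systolic pressure is not
#' reported for that cohort; the default N(135, 18) mmHg, combined with
#' the diastolic model, makes the blood-pressure hypertension rule flag
#' about 67.5% of patients, matching the reported hypertension rate. The
#' AHI marginal uses the shifted-gamma family so mean, SD and prevalence
#' hold simultaneously (a normal AHI with this mean and SD would imply a
#' 69.5% prevalence).
#'
#' @param n Number of patients (default 2595, the reference cohort size).
#' @param seed Master integer seed.
#' @return A `cohort_spec`.
#' @export
westro_cohort_spec <- function(n = 2595, seed = 1L) {
  cohort_spec(
    n = n, seed = seed, male_frac = 0.692,
    marginals = list(age = c(52.2, 13.25), bmi = c(33.73, 7.11),
                     neck_cm = c(43.15, 5.25), sys_bp = c(135, 18),
                     ess = c(11.16, 5.40), ahi = c(43.54, 26.57)),
    loadings = c(age = 0.2, bmi = 0.5, neck_cm = 0.5, sys_bp = 0.3,
                 ess = 0.5, ahi = 0.8),
    symptom_rates = c(snoring = 0.780, tiredness = 0.659, observed_apnea = 0.55),
    target_prevalence = 0.644,
    ahi_family = "gamma"
  )
}

# Solve the logistic intercept a so that E[plogis(a + slope * z)] = rate
# under z ~ N(0, 1) (Gauss quadrature on a fine grid).
symptom_intercept <- function(rate, slope) {
  if (rate <= 0 || rate >= 1) stop_config("symptom rates must lie strictly in (0, 1)")
  z <- seq(-8, 8, length.out = 4001)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  uniroot(function(a) sum(w * plogis(a + slope * z)) - rate,
          interval = c(-30, 30), tol = 1e-10)$root
}

# Shifted-gamma AHI parameters matching mean m, sd s and P(AHI >= thr) = p:
# AHI = shift + Gamma(shape, scale), shape solved by root finding. The
# normal limit (shape -> Inf) bounds the attainable prevalence from above
# when p exceeds the symmetric value.
ahi_gamma_params <- function(m, s, p, thr = 30) {
  f <- function(k) {
    th <- s / sqrt(k)
    shift <- m - k * th
    1 - pgamma(pmax(thr - shift, 0), shape = k, scale = th) - p
  }
  # f is not monotone over all k (at tiny shapes the shift exceeds the
  # threshold), so locate a sign change on a log grid before root finding
  ks <- exp(seq(log(0.05), log(500), length.out = 200))
  fv <- vapply(ks, f, numeric(1))
  sign_change <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (length(sign_change) == 0) {
    stop_config(paste0(
      "no shifted-gamma AHI marginal matches this mean/SD/prevalence ",
      "combination; use ahi_family = 'normal' with calibrate_prevalence()"))
  }
  i <- utils::tail(sign_change, 1)
  k <- uniroot(f, c(ks[i], ks[i + 1]), tol = 1e-10)$root
  th <- s / sqrt(k)
  list(shape = k, scale = th, shift = m - k * th)
}

clip_count <- function(x, bounds) {
  clipped <- sum(x < bounds[1] | x > bounds[2])
  list(x = pmin(pmax(x, bounds[1]), bounds[2]), clipped = clipped)
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort from a [cohort_spec()] under its single-latent-factor
#' model. The draw is fully determined by the spec's seed (the caller's RNG
#' state is untouched): the same spec yields a bit-identical cohort. The
#' Epworth score is rounded to an integer and clipped to 0-24; all
#' measurements are clipped to the spec's plausibility bounds, with clip
#' counts reported. The hypertension flag is derived from the generated
#' pressures via the blood-pressure rule.
#'
#' @param spec A `cohort_spec`.
#' @return A canonical cohort tibble (see [read_cohort()]) with a
#'   `"generator_report"` attribute, retrievable with [generator_report()]:
#'   realized marginal means/SDs, realized prevalence of AHI >= 30, the
#'   Spearman correlation between the SAS score and AHI, and clip counts.
#' @export
#' @examples
#' cohort <- generate_cohort(westro_cohort_spec(n = 200, seed = 42))
#' generator_report(cohort)$prevalence
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n
  vars <- c("age", "bmi", "neck_cm", "sys_bp", "ess")
  if (n == 0) {
    cohort <- tibble(
      id = character(), sex = character(), age = numeric(), bmi = numeric(),
      neck_cm = numeric(), sys_bp = numeric(), dia_bp = numeric(),
      ess = integer(), hypertension = logical(), snoring = logical(),
      tiredness = logical(), observed_apnea = logical(), ahi = numeric()
    )
    attr(cohort, "provenance") <- "generate_cohort(n = 0)"
    return(cohort)
  }

  gamma_par <- if (spec$ahi_family == "gamma") {
    ahi_gamma_params(spec$marginals$ahi[1], spec$marginals$ahi[2],
                     spec$target_prevalence)
  }

  out <- withr::with_seed(spec$seed, {
    male <- rbinom(n, 1, spec$male_frac) == 1
    z <- rnorm(n)
    clips <- c()
    draw_cont <- function(var) {
      m <- spec$marginals[[var]]
      lam <- spec$loadings[[var]]
      x <- m[1] + m[2] * (lam * z + sqrt(1 - lam^2) * rnorm(n))
      if (var == "neck_cm") {
        x <- x + spec$male_nc_shift * (male - spec$male_frac)
      }
      cc <- clip_count(x, spec$clip[[var]])
      clips[[var]] <<- cc$clipped
      cc$x
    }
    vals <- lapply(setNames(vars, vars), draw_cont)

    lam <- spec$loadings[["ahi"]]
    u <- lam * z + sqrt(1 - lam^2) * rnorm(n)
    ahi <- if (spec$ahi_family == "gamma") {
      gamma_par$shift + qgamma(pnorm(u), shape = gamma_par$shape,
                               scale = gamma_par$scale)
    } else {
      spec$marginals$ahi[1] + spec$marginals$ahi[2] * u
    }
    cc <- clip_count(ahi, spec$clip$ahi)
    clips[["ahi"]] <- cc$clipped
    ahi <- cc$x

    ess <- round(vals$ess)
    cc <- clip_count(ess, spec$clip$ess)
    clips[["ess"]] <- clips[["ess"]] + cc$clipped
    ess <- as.integer(cc$x)

    dia <- spec$dia_intercept + spec$dia_slope * vals$sys_bp + rnorm(n, 0, spec$dia_sd)
    cc <- clip_count(dia, spec$clip$dia_bp)
    clips[["dia_bp"]] <- cc$clipped
    dia <- cc$x

    symptoms <- lapply(setNames(names(spec$symptom_rates), names(spec$symptom_rates)),
      function(s) {
        a <- symptom_intercept(spec$symptom_rates[[s]], spec$symptom_slope)
        rbinom(n, 1, plogis(a + spec$symptom_slope * z)) == 1
      })

    list(male = male, vals = vals, ahi = ahi, ess = ess, dia = dia,
         symptoms = symptoms, clips = clips)
  })

  cohort <- tibble(
    id = sprintf("syn%06d", seq_len(n)),
    sex = ifelse(out$male, "male", "female"),
    age = out$vals$age,
    bmi = out$vals$bmi,
    neck_cm = out$vals$neck_cm,
    sys_bp = out$vals$sys_bp,
    dia_bp = out$dia,
    ess = out$ess,
    hypertension = hypertension_from_bp(out$vals$sys_bp, out$dia),
    snoring = out$symptoms$snoring,
    tiredness = out$symptoms$tiredness,
    observed_apnea = out$symptoms$observed_apnea,
    ahi = out$ahi
  )

  n_clipped <- sum(unlist(out$clips))
  if (n_clipped > 0) {
    inform(sprintf("clipped %d generated value(s) to plausibility bounds", n_clipped))
  }

  scored <- score_sas(cohort)
  realized <- purrr::map_dfr(c(vars, "ahi"), function(v) {
    tibble(variable = v, mean = mean(cohort[[v]]), sd = sd(cohort[[v]]))
  })
  report <- list(
    realized = realized,
    prevalence = mean(cohort$ahi >= 30),
    male_frac = mean(cohort$sex == "male"),
    symptom_rates = vapply(names(spec$symptom_rates),
                           function(s) mean(cohort[[s]]), numeric(1)),
    hypertension_rate = mean(cohort$hypertension),
    spearman_sas_ahi = if (sd(cohort$ahi) > 0 && sd(scored$sas_score) > 0) {
      cor(scored$sas_score, cohort$ahi, method = "spearman")
    } else NA_real_, # degenerate draw (e.g. fully clipped AHI)
    clipped = unlist(out$clips)
  )
  attr(cohort, "provenance") <- sprintf("generate_cohort(seed = %d, n = %d)",
                                        spec$seed, n)
  attr(cohort, "generator_report") <- report
  cohort
}

#' @rdname generate_cohort
#' @param cohort A cohort generated by [generate_cohort()].
#' @export
generator_report <- function(cohort) {
  attr(cohort, "generator_report")
}

#' Calibrate a cohort spec to its target prevalence
#'
#' Adjusts the AHI marginal mean (holding the SD) by bisection until the
#' realized prevalence of AHI >= 30 on a large pilot draw is within
#' `tolerance` of `target_prevalence`. The pilot draw uses common random
#' numbers (the spec's seed), so the search is deterministic. A spec
#' already on target — in particular any `ahi_family = "gamma"` spec,
#' which matches prevalence by construction — is returned unchanged.
#'
#' @param spec A `cohort_spec`.
#' @param tolerance Acceptable absolute prevalence gap (> 0, default 0.01).
#' @param pilot_n Pilot draw size (default 20000).
#' @param max_iter Bisection iteration cap (default 50).
#' @return The spec with its AHI mean adjusted.
#' @export
calibrate_prevalence <- function(spec, tolerance = 0.01, pilot_n = 20000,
                                 max_iter = 50) {
  validate_cohort_spec(spec)
  if (tolerance <= 0) stop_config("tolerance must be > 0")
  realized_at <- function(m) {
    s2 <- spec
    s2$marginals$ahi[1] <- m
    s2$n <- pilot_n
    if (s2$ahi_family == "gamma") {
      # bisection targets the mean, so prevalence must respond to it:
      # hold the gamma shape/scale solved at the current mean
      gp <- tryCatch(ahi_gamma_params(m, s2$marginals$ahi[2], s2$target_prevalence),
                     error = function(e) NULL)
      if (is.null(gp)) s2$ahi_family <- "normal"
    }
    suppressMessages(mean(generate_cohort(s2)$ahi >= 30))
  }
  m0 <- spec$marginals$ahi[1]
  target <- spec$target_prevalence
  if (abs(realized_at(m0) - target) <= tolerance) {
    return(spec)
  }
  s <- spec$marginals$ahi[2]
  lo <- m0 - 6 * s
  hi <- m0 + 6 * s
  if ((realized_at(lo) - target) * (realized_at(hi) - target) > 0) {
    abort(sprintf("prevalence target %.3f unreachable within +/- 6 SD of the AHI mean",
                  target), class = "sasscreen_calibration_error")
  }
  gap <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- realized_at(mid)
    gap <- r - target
    if (abs(gap) <= tolerance) {
      spec$marginals$ahi[1] <- mid
      return(spec)
    }
    if (gap > 0) hi <- mid else lo <- mid
  }
  abort(sprintf("prevalence calibration did not converge: achieved gap %.4f after %d iterations",
                gap, max_iter), class = "sasscreen_calibration_error")
}
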