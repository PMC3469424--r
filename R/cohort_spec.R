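#' Specification of a synthetic health-check cohort
#'
#' A `cohort_spec` collects every parameter of the synthetic cohort
#' generator: marginal distributions of the baseline characteristics,
#' lifestyle-habit prevalences, the habit/age effects that drive the
#' gamma-GTP and white-blood-cell (WBC) distributions, the logistic onset
#' model for metabolic syndrome (MetS) during follow-up, follow-up drift
#' and noise, per-characteristic missingness, and the random seed.
#'
#' Two presets ship with the package:
#' \describe{
#'   \item{`"original"`}{An employee cohort of young adult men
#'     (age ~ 31 +/- 6 y, n = 1803 by default) whose healthy-stratum
#'     gamma-GTP mean sits near 16 IU/L.}
#'   \item{`"replication"`}{An older cohort (age ~ 43 +/- 7 y,
#'     n = 4400 by default) whose healthy-stratum gamma-GTP mean sits near
#'     27 IU/L, the shift being driven entirely by the age effect on the
#'     log gamma-GTP scale.}
#' }
#'
#' Continuous characteristics are normal, truncated at physiologic floors,
#' except gamma-GTP and triglycerides which are log-normal (both are
#' strongly right-skewed in health-check data). Habitual drinking shifts
#' log gamma-GTP additively; habitual smoking shifts WBC additively; age
#' enters log gamma-GTP linearly. MetS onset during follow-up is a single
#' Bernoulli event per subject with logistic probability in standardized
#' log gamma-GTP, standardized WBC, and their product.
#'
#' @param preset `"original"` or `"replication"`.
#' @param n_subjects Number of subjects (overrides the preset default).
#' @param follow_up_years Number of annual follow-up panels (default 8).
#' @param seed Integer seed for all generator randomness.
#' @param ... Named overrides for any spec field (e.g. `onset = list(...)`,
#'   `missingness = c(ggt = 0)`). List fields are merged element-wise.
#'
#' @return An object of class `cohort_spec` (a named list).
#' @export
#' @examples
#' spec <- cohort_spec("original", n_subjects = 500, seed = 1)
#' spec$onset$b_interaction
cohort_spec <- function(preset = c("original", "replication"),
                        n_subjects = NULL,
                        follow_up_years = 8L,
                        seed = 1L,
                        ...) {
  preset <- match.arg(preset)

  spec <- list(
    preset = preset,
    n_subjects = if (preset == "original") 1803L else 4400L,
    follow_up_years = as.integer(follow_up_years),
    seed = as.integer(seed),

    # age (years); reference age anchors the age effect on log gamma-GTP
    age = list(mean = if (preset == "original") 31 else 43,
               sd = if (preset == "original") 6 else 7,
               floor = 18),
    age_ref = 31,

    # anthropometrics: weight is derived from BMI and height
    height = list(mean = 171, sd = 5.5, floor = 140),
    bmi    = list(mean = 21.0, sd = 2.0, floor = 15),

    # blood pressure; SBP/DBP correlated
    sbp = list(mean = 126, sd = 13, floor = 70),
    dbp = list(mean = 77, sd = 9.5, floor = 40),
    bp_corr = 0.6,

    # lipids and glucose (MetS components); TG log-normal
    tc      = list(mean = 178, sd = 26, floor = 80),
    tg      = list(meanlog = log(95), sdlog = 0.48),
    hdl     = list(mean = 53.5, sd = 11.5, floor = 15),
    glucose = list(mean = 93.5, sd = 8.5, floor = 50),

    # the non-component candidate characteristics
    bun        = list(mean = 14, sd = 3.5, floor = 3),
    creatinine = list(mean = 0.9, sd = 0.13, floor = 0.3),
    uric_acid  = list(mean = 5.8, sd = 1.2, floor = 1),
    hemoglobin = list(mean = 15.2, sd = 1.0, floor = 8),
    got        = list(mean = 22, sd = 8, floor = 5),
    gpt        = list(mean = 25, sd = 14, floor = 3),
    hematocrit = list(mean = 45, sd = 3, floor = 20),
    rbc        = list(mean = 4.9, sd = 0.35, floor = 2.5),

    # gamma-GTP: log-normal with drinking and age effects (log scale)
    ggt = list(meanlog = 2.307, sdlog = 0.5,
               alcohol_shift = 0.38,   # log-scale shift in drinkers
               age_slope = 0.040),     # per year of age
    # WBC (cells/uL): normal with additive smoking shift
    wbc = list(mean = 5700, sd = 1400, smoking_shift = 1150, floor = 1500),

    # habit prevalences
    prevalence = list(alcohol = 0.85, smoking = 0.56,
                      exercise = c(none = 0.50, once = 0.20,
                                   twice = 0.20, daily = 0.10)),

    # urinalysis flags: Bernoulli noise
    urine = c(urine_urobilinogen = 0.04, urine_protein = 0.05,
              urine_sugar = 0.02, urine_occult_blood = 0.04),

    # medication flags (subjects on these are excluded from analysis)
    medication = c(med_antihypertensive = 0.02, med_lipid_lowering = 0.015,
                   med_antidiabetic = 0.01),

    # MetS onset model: logit P = b0 + b1*z(log gGTP) + b2*z(WBC) + b12*z*z
    onset = list(b0 = -4.5, b_ggt = 1.3, b_wbc = 0.91, b_interaction = 0.45),

    # follow-up dynamics: annual drift (aging) and exam-to-exam noise
    followup = list(
      drift = c(bmi = 0.03, sbp = 0.30, dbp = 0.25, tg_log = 0.008,
                hdl = -0.15, glucose = 0.30),
      noise = c(bmi = 0.20, sbp = 6.5, dbp = 5.0, tg_log = 0.15,
                hdl = 3.5, glucose = 4.5),
      # increments applied from the onset year onward for onset subjects
      onset_bmi_min = 25.2, onset_sbp_min = 131, onset_tg_min = 155
    ),

    # MCAR missingness of the candidate inputs (fractions in [0,1))
    missingness = c(smoking = 0.01, bun = 0.12, creatinine = 0.12,
                    uric_acid = 0.12, ggt = 0.26, hemoglobin = 0.12,
                    got = 0.15, gpt = 0.15, hematocrit = 0.12, rbc = 0.12,
                    wbc = 0.21, urine_urobilinogen = 0.10,
                    urine_protein = 0.10, urine_sugar = 0.10,
                    urine_occult_blood = 0.10, alcohol = 0.01)
  )

  if (!is.null(n_subjects)) spec$n_subjects <- as.integer(n_subjects)

  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(spec)) stop("unknown cohort_spec field: ", nm)
    if (is.list(spec[[nm]]) && is.list(dots[[nm]])) {
      spec[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else if (!is.null(names(dots[[nm]])) && !is.null(names(spec[[nm]]))) {
      spec[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      spec[[nm]] <- dots[[nm]]
    }
  }

  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.na(spec$n_subjects) || spec$n_subjects < 0)
    stop("n_subjects must be >= 0")
  if (spec$follow_up_years < 1) stop("follow_up_years must be >= 1")
  sds <- c(spec$age$sd, spec$height$sd, spec$bmi$sd, spec$sbp$sd,
           spec$dbp$sd, spec$tc$sd, spec$tg$sdlog, spec$hdl$sd,
           spec$glucose$sd, spec$bun$sd, spec$creatinine$sd,
           spec$uric_acid$sd, spec$hemoglobin$sd, spec$got$sd, spec$gpt$sd,
           spec$hematocrit$sd, spec$rbc$sd, spec$ggt$sdlog, spec$wbc$sd)
  if (any(sds <= 0)) stop("all spec standard deviations must be positive")
  prev <- c(spec$prevalence$alcohol, spec$prevalence$smoking,
            spec$prevalence$exercise, spec$urine, spec$medication)
  if (any(prev < 0 | prev > 1)) stop("prevalences must lie in [0, 1]")
  if (abs(sum(spec$prevalence$exercise) - 1) > 1e-8)
    stop("exercise category probabilities must sum to 1")
  if (any(spec$missingness < 0 | spec$missingness >= 1))
    stop("missingness rates must lie in [0, 1)")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$preset, "preset:",
      x$n_subjects, "subjects,", x$follow_up_years, "follow-up years, seed",
      x$seed, "\n")
  cat("  onset logit: ", x$onset$b0, " + ", x$onset$b_ggt,
      "*z(log gGTP) + ", x$onset$b_wbc, "*z(WBC) + ",
      x$onset$b_interaction, "*interaction\n", sep = "")
  invisible(x)
}

# names of the candidate FNN inputs, in their conventional input order
#' Candidate input characteristics for FNN feature selection
#'
#' The sixteen routine health-check characteristics offered to forward
#' selection: lifestyle habits, renal markers, serum enzymes, hematology
#' and urinalysis flags. None of them enters the MetS definition itself.
#'
#' @return Character vector of 16 column names, in input-number order
#'   (ties in model selection are broken toward the lower index).
#' @export
candidate_inputs <- function() {
  c("smoking", "bun", "creatinine", "uric_acid", "ggt", "hemoglobin",
    "got", "gpt", "hematocrit", "rbc", "wbc", "urine_urobilinogen",
    "urine_protein", "urine_sugar", "urine_occult_blood", "alcohol")
}

# theoretical (population) mean and sd of log gamma-GTP and WBC under a
# spec; used to standardize the onset model so its coefficients are
# per-SD log-odds regardless of sample.
latent_moments <- function(spec) {
  p_a <- spec$prevalence$alcohol
  p_s <- spec$prevalence$smoking
  g <- spec$ggt
  m1 <- g$meanlog + p_a * g$alcohol_shift +
    g$age_slope * (spec$age$mean - spec$age_ref)
  s1 <- sqrt(g$sdlog^2 + g$alcohol_shift^2 * p_a * (1 - p_a) +
               (g$age_slope * spec$age$sd)^2)
  w <- spec$wbc
  m2 <- w$mean + p_s * w$smoking_shift
  s2 <- sqrt(w$sd^2 + w$smoking_shift^2 * p_s * (1 - p_s))
  list(ggt_log = c(mean = m1, sd = s1), wbc = c(mean = m2, sd = s2))
}
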