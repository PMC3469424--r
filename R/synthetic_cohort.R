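# Synthetic cohort generation: baseline characteristics, follow-up MetS
# component panels, and MCAR missingness. All randomness is seeded from
# spec$seed with a fixed per-stage offset, so generate -> followup ->
# missingness is reproducible stage by stage.

rnorm_floor <- function(n, par) pmax(stats::rnorm(n, par$mean, par$sd), par$floor)

#' Generate baseline health-check records
#'
#' Draws one baseline record per subject: anthropometrics (weight derived
#' from BMI and height so the two are always consistent), blood pressure
#' (SBP/DBP correlated), serum biochemistry, hematology, urinalysis flags,
#' lifestyle habits and medication flags. Gamma-GTP is log-normal with
#' additive log-scale shifts for habitual drinking and age; WBC is normal
#' with an additive shift in smokers.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per subject. Columns include
#'   `subject_id`, `age`, `height`, `weight`, `bmi`, `sbp`, `dbp`, `tc`,
#'   `tg`, `hdl`, `glucose`, the 16 candidate inputs (see
#'   [candidate_inputs()]), `exercise`, and three medication flags.
#' @export
#' @examples
#' b <- generate_baseline(cohort_spec("original", n_subjects = 100, seed = 7))
#' nrow(b)
generate_baseline <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  cols <- c("subject_id", "age", "height", "weight", "bmi", "sbp", "dbp",
            "tc", "tg", "hdl", "glucose", candidate_inputs(), "exercise",
            names(spec$medication))
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(cols),
                                dimnames = list(NULL, cols)))
    out$exercise <- character(0)
    return(out)
  }
  set.seed(spec$seed)

  age <- pmax(stats::rnorm(n, spec$age$mean, spec$age$sd), spec$age$floor)
  height <- rnorm_floor(n, spec$height)
  bmi <- rnorm_floor(n, spec$bmi)
  weight <- bmi * (height / 100)^2

  sbp_z <- stats::rnorm(n)
  sbp <- pmax(spec$sbp$mean + spec$sbp$sd * sbp_z, spec$sbp$floor)
  r <- spec$bp_corr
  dbp <- pmax(spec$dbp$mean +
                spec$dbp$sd * (r * sbp_z + sqrt(1 - r^2) * stats::rnorm(n)),
              spec$dbp$floor)

  tc <- rnorm_floor(n, spec$tc)
  tg <- stats::rlnorm(n, spec$tg$meanlog, spec$tg$sdlog)
  hdl <- rnorm_floor(n, spec$hdl)
  glucose <- rnorm_floor(n, spec$glucose)

  alcohol <- stats::rbinom(n, 1, spec$prevalence$alcohol)
  smoking <- stats::rbinom(n, 1, spec$prevalence$smoking)
  exercise <- sample(names(spec$prevalence$exercise), n, replace = TRUE,
                     prob = spec$prevalence$exercise)

  g <- spec$ggt
  ggt <- exp(g$meanlog + g$alcohol_shift * alcohol +
               g$age_slope * (age - spec$age_ref) +
               stats::rnorm(n, 0, g$sdlog))
  w <- spec$wbc
  wbc <- pmax(w$mean + w$smoking_shift * smoking + stats::rnorm(n, 0, w$sd),
              w$floor)

  out <- data.frame(
    subject_id = seq_len(n),
    age = age, height = height, weight = weight, bmi = bmi,
    sbp = sbp, dbp = dbp, tc = tc, tg = tg, hdl = hdl, glucose = glucose,
    smoking = smoking,
    bun = rnorm_floor(n, spec$bun),
    creatinine = rnorm_floor(n, spec$creatinine),
    uric_acid = rnorm_floor(n, spec$uric_acid),
    ggt = ggt,
    hemoglobin = rnorm_floor(n, spec$hemoglobin),
    got = rnorm_floor(n, spec$got),
    gpt = rnorm_floor(n, spec$gpt),
    hematocrit = rnorm_floor(n, spec$hematocrit),
    rbc = rnorm_floor(n, spec$rbc),
    wbc = wbc,
    alcohol = alcohol,
    exercise = exercise,
    stringsAsFactors = FALSE
  )
  for (u in names(spec$urine)) out[[u]] <- stats::rbinom(n, 1, spec$urine[[u]])
  for (m in names(spec$medication))
    out[[m]] <- stats::rbinom(n, 1, spec$medication[[m]])
  out[, cols]
}

#' Per-subject MetS onset probability under the spec's logistic model
#'
#' Computes, independently of the follow-up simulation's random draws, the
#' probability that a subject develops metabolic syndrome during follow-up:
#' `plogis(b0 + b1*z1 + b2*z2 + b12*z1*z2)` where `z1` is standardized
#' log gamma-GTP and `z2` standardized WBC (standardization constants are
#' the spec's theoretical population moments, so coefficients are log-odds
#' per SD).
#'
#' @param baseline Baseline data frame from [generate_baseline()].
#' @param spec The [cohort_spec()].
#' @return Numeric vector of probabilities, one per subject.
#' @export
onset_probability <- function(baseline, spec) {
  mom <- latent_moments(spec)
  z1 <- (log(baseline$ggt) - mom$ggt_log["mean"]) / mom$ggt_log["sd"]
  z2 <- (baseline$wbc - mom$wbc["mean"]) / mom$wbc["sd"]
  o <- spec$onset
  unname(stats::plogis(o$b0 + o$b_ggt * z1 + o$b_wbc * z2 +
                         o$b_interaction * z1 * z2))
}

#' Simulate annual follow-up MetS-component panels
#'
#' Each subject receives `spec$follow_up_years` annual panels of the six
#' MetS components (BMI, SBP, DBP, TG, HDL, fasting glucose). Year-to-year
#' values follow the baseline plus a cumulative aging drift plus
#' exam-to-exam noise (TG on the log scale). Whether a subject develops
#' MetS is a single Bernoulli event with probability [onset_probability()];
#' for onset subjects a uniformly chosen onset year starts a persistent
#' elevation that guarantees the JASSO criteria (obesity plus raised blood
#' pressure and dyslipidemia) from that year onward.
#'
#' @param baseline Data frame from [generate_baseline()].
#' @param spec The [cohort_spec()].
#' @return An object of class `mets_cohort`: a list with `$baseline`,
#'   `$followup` (long data frame: `subject_id`, `year`, six components),
#'   and `$spec`.
#' @export
simulate_followup <- function(baseline, spec) {
  validate_cohort_spec(spec)
  n <- nrow(baseline)
  yrs <- spec$follow_up_years
  set.seed(spec$seed + 1L)

  onset <- if (n > 0) stats::rbinom(n, 1, onset_probability(baseline, spec)) else integer(0)
  onset_year <- ifelse(onset == 1, sample.int(yrs, n, replace = TRUE), NA_integer_)

  fu <- spec$followup
  drift <- fu$drift; noise <- fu$noise

  rows <- vector("list", yrs)
  for (t in seq_len(yrs)) {
    bmi <- pmax(baseline$bmi + drift["bmi"] * t +
                  stats::rnorm(n, 0, noise["bmi"]), 12)
    sbp <- pmax(baseline$sbp + drift["sbp"] * t +
                  stats::rnorm(n, 0, noise["sbp"]), 70)
    dbp <- pmax(baseline$dbp + drift["dbp"] * t +
                  stats::rnorm(n, 0, noise["dbp"]), 40)
    tg <- baseline$tg * exp(drift["tg_log"] * t +
                              stats::rnorm(n, 0, noise["tg_log"]))
    hdl <- pmax(baseline$hdl + drift["hdl"] * t +
                  stats::rnorm(n, 0, noise["hdl"]), 10)
    glucose <- pmax(baseline$glucose + drift["glucose"] * t +
                      stats::rnorm(n, 0, noise["glucose"]), 45)

    hit <- !is.na(onset_year) & onset_year <= t
    if (any(hit)) {
      k <- sum(hit)
      bmi[hit] <- pmax(bmi[hit], fu$onset_bmi_min + abs(stats::rnorm(k, 0.6, 0.5)))
      sbp[hit] <- pmax(sbp[hit], fu$onset_sbp_min + abs(stats::rnorm(k, 4, 4)))
      tg[hit] <- pmax(tg[hit], fu$onset_tg_min + abs(stats::rnorm(k, 30, 25)))
    }
    rows[[t]] <- data.frame(subject_id = baseline$subject_id, year = t,
                            bmi = bmi, sbp = sbp, dbp = dbp, tg = tg,
                            hdl = hdl, glucose = glucose)
  }
  followup <- do.call(rbind, rows)
  followup <- followup[order(followup$subject_id, followup$year), ,
                       drop = FALSE]
  rownames(followup) <- NULL
  structure(list(baseline = baseline, followup = followup, spec = spec),
            class = "mets_cohort")
}

#' @export
print.mets_cohort <- function(x, ...) {
  cat("<mets_cohort>", nrow(x$baseline), "subjects x",
      x$spec$follow_up_years, "follow-up years (", x$spec$preset,
      "preset, seed", x$spec$seed, ")\n")
  if ("label" %in% names(x$baseline))
    print(table(x$baseline$label))
  invisible(x)
}

#' Inject missing-completely-at-random entries into candidate inputs
#'
#' Each candidate characteristic is independently set to `NA` at its
#' spec missingness rate. Follow-up component panels are untouched: cohort
#' labeling requires complete panels, and the varying analysis n arises
#' from missingness in the candidate inputs themselves.
#'
#' @param x A `mets_cohort` or a baseline data frame.
#' @param spec The [cohort_spec()]; defaults to `x$spec` for a cohort.
#' @param rates Optional named vector overriding `spec$missingness`.
#' @return Object of the same type with `NA`s injected.
#' @export
inject_missingness <- function(x, spec = NULL, rates = NULL) {
  is_cohort <- inherits(x, "mets_cohort")
  if (is.null(spec)) {
    if (!is_cohort) stop("spec must be supplied for a bare data frame")
    spec <- x$spec
  }
  if (is.null(rates)) rates <- spec$missingness
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must lie in [0, 1)")
  df <- if (is_cohort) x$baseline else x
  set.seed(spec$seed + 2L)
  for (nm in names(rates)) {
    if (!nm %in% names(df) || rates[[nm]] == 0) next
    df[[nm]][stats::runif(nrow(df)) < rates[[nm]]] <- NA
  }
  if (is_cohort) { x$baseline <- df; x } else df
}

#' Generate a complete labeled synthetic cohort
#'
#' Convenience wrapper: baseline, follow-up simulation, missingness
#' injection and cohort labeling in one call.
#'
#' @param spec A [cohort_spec()].
#' @param missing Logical; inject missingness (default `TRUE`).
#' @param label Logical; append cohort labels (default `TRUE`).
#' @return A `mets_cohort`; if `label = TRUE` its baseline carries a
#'   `label` column (`case` / `healthy_control` / `normal_control` /
#'   `excluded`).
#' @export
#' @examples
#' ch <- generate_cohort(cohort_spec("original", n_subjects = 300, seed = 2))
#' table(ch$baseline$label)
generate_cohort <- function(spec, missing = TRUE, label = TRUE) {
  baseline <- generate_baseline(spec)
  cohort <- simulate_followup(baseline, spec)
  if (missing) cohort <- inject_missingness(cohort)
  if (label) cohort <- label_cohort(cohort)
  cohort
}
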