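# JASSO-based metabolic syndrome classification and cohort labeling.
#
# Obesity is mandatory: waist circumference >= 85 cm, or BMI >= 25 kg/m^2
# when waist was not measured (the BMI-modified definition; synthetic
# cohorts carry no waist measurement). MetS = obesity plus any two of
# raised blood pressure, dyslipidemia, raised fasting glucose. All
# boundaries are inclusive as printed (>= 130/>= 85 mmHg, TG >= 150,
# HDL < 40, glucose >= 110 mg/dL).

#' JASSO component flags for one examination panel
#'
#' @param panel A list or one-row data frame with any of `waist`, `bmi`,
#'   `sbp`, `dbp`, `tg`, `hdl`, `glucose`. Missing entries are `NA`.
#' @return A list of class `component_flags`: logical `obesity`,
#'   `raised_bp`, `dyslipidemia`, `raised_glucose` (each `NA` when
#'   undeterminable) and `n_components` (`NA` when any flag is `NA`).
#' @export
#' @examples
#' component_flags(list(bmi = 26, sbp = 135, dbp = 80, tg = 160,
#'                      hdl = 50, glucose = 100))
component_flags <- function(panel) {
  g <- function(nm) {
    v <- panel[[nm]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[[1]])
  }
  waist <- g("waist"); bmi <- g("bmi")
  sbp <- g("sbp"); dbp <- g("dbp")
  tg <- g("tg"); hdl <- g("hdl"); glucose <- g("glucose")

  obesity <- if (!is.na(waist)) waist >= 85
             else if (!is.na(bmi)) bmi >= 25 else NA
  # "and/or": one raised observed value suffices for TRUE; FALSE needs
  # both observed; otherwise indeterminate
  raised_bp <- or_na(!is.na(sbp) && sbp >= 130, !is.na(dbp) && dbp >= 85,
                     is.na(sbp) || is.na(dbp))
  dyslipidemia <- or_na(!is.na(tg) && tg >= 150, !is.na(hdl) && hdl < 40,
                        is.na(tg) || is.na(hdl))
  raised_glucose <- if (!is.na(glucose)) glucose >= 110 else NA

  if (is.na(obesity) && is.na(raised_bp) && is.na(dyslipidemia) &&
      is.na(raised_glucose))
    stop("panel has no determinable MetS component")

  flags <- c(obesity = obesity, raised_bp = raised_bp,
             dyslipidemia = dyslipidemia, raised_glucose = raised_glucose)
  structure(c(as.list(flags),
              list(n_components = if (anyNA(flags)) NA_integer_
                                  else sum(flags))),
            class = "component_flags")
}

# TRUE if either observed branch is TRUE; NA if no TRUE and any side
# unobserved; FALSE only when both sides are observed and below threshold.
or_na <- function(a, b, any_missing) {
  if (isTRUE(a) || isTRUE(b)) TRUE else if (any_missing) NA else FALSE
}

#' Is a panel's component pattern metabolic syndrome?
#'
#' @param flags A `component_flags` object (or list with the four logical
#'   flags).
#' @return `TRUE` iff obesity and at least two of the other three
#'   components; `NA` when the decision depends on an undeterminable flag.
#' @export
is_mets <- function(flags) {
  ob <- flags$obesity
  others <- c(flags$raised_bp, flags$dyslipidemia, flags$raised_glucose)
  if (isFALSE(ob)) return(FALSE)
  n_true <- sum(others, na.rm = TRUE)
  n_na <- sum(is.na(others))
  if (isTRUE(ob)) {
    if (n_true >= 2) return(TRUE)
    if (n_true + n_na < 2) return(FALSE)
    return(NA)
  }
  # obesity undeterminable: MetS only possible, never certain
  if (n_true >= 2) NA else if (n_true + n_na < 2) FALSE else NA
}

#' Label one subject from baseline and follow-up panels
#'
#' Labels are assigned in priority order: `excluded` if any medication
#' flag (antihypertensive, lipid-lowering, anti-diabetic) is set or if the
#' subject already meets MetS criteria at baseline (cases must *develop*
#' MetS); `case` if MetS criteria are met in any follow-up year;
#' `healthy_control` if the subject is component-free (a "supercontrol")
#' at baseline and in every follow-up year, which requires all five
#' component measurements observed in each panel; otherwise
#' `normal_control`.
#'
#' @param baseline_panel Baseline measurements (list/one-row data frame).
#' @param followup_panels Data frame of follow-up panels, one row per year.
#' @param medicated Logical: any exclusion medication flag set.
#' @return One of `"case"`, `"healthy_control"`, `"normal_control"`,
#'   `"excluded"`.
#' @export
assign_cohort_label <- function(baseline_panel, followup_panels, medicated) {
  if (is.null(followup_panels) || nrow(followup_panels) == 0)
    stop("at least one follow-up panel is required")
  if (isTRUE(medicated)) return("excluded")

  base_flags <- component_flags(baseline_panel)
  if (isTRUE(is_mets(base_flags))) return("excluded")

  panels <- lapply(seq_len(nrow(followup_panels)),
                   function(i) component_flags(followup_panels[i, ]))
  mets_any <- vapply(panels, function(f) isTRUE(is_mets(f)), logical(1))
  if (any(mets_any)) return("case")

  # supercontrol throughout: zero components, fully observed, every panel
  clean <- function(f) !is.na(f$n_components) && f$n_components == 0
  if (clean(base_flags) && all(vapply(panels, clean, logical(1))))
    return("healthy_control")
  "normal_control"
}

#' Append cohort labels to a synthetic cohort
#'
#' Vectorized driver of [assign_cohort_label()] over a `mets_cohort`.
#'
#' @param cohort A `mets_cohort` from [simulate_followup()] or
#'   [generate_cohort()].
#' @return The cohort with a `label` column added to `$baseline`.
#' @export
label_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "mets_cohort"))
  b <- cohort$baseline
  if (nrow(b) == 0) { b$label <- character(0); cohort$baseline <- b; return(cohort) }
  med_cols <- intersect(c("med_antihypertensive", "med_lipid_lowering",
                          "med_antidiabetic"), names(b))
  medicated <- if (length(med_cols))
    rowSums(b[, med_cols, drop = FALSE], na.rm = TRUE) > 0
  else rep(FALSE, nrow(b))
  fu_split <- split(cohort$followup, cohort$followup$subject_id)
  b$label <- vapply(seq_len(nrow(b)), function(i) {
    assign_cohort_label(b[i, ], fu_split[[as.character(b$subject_id[i])]],
                        medicated[i])
  }, character(1))
  cohort$baseline <- b
  cohort
}

#' Case / healthy-control analysis table
#'
#' Restricts a labeled cohort to the two analysis strata and adds the
#' numeric target coding used by the FNN (`+1` case, `-1` control).
#'
#' @param cohort A labeled `mets_cohort` (or its baseline data frame with
#'   a `label` column).
#' @return Data frame of case and healthy-control subjects with a `target`
#'   column.
#' @export
analysis_table <- function(cohort) {
  b <- if (inherits(cohort, "mets_cohort")) cohort$baseline else cohort
  if (!"label" %in% names(b)) stop("cohort is not labeled; run label_cohort()")
  b <- b[b$label %in% c("case", "healthy_control"), , drop = FALSE]
  b$target <- ifelse(b$label == "case", 1, -1)
  rownames(b) <- NULL
  b
}
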