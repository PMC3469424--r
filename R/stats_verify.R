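# Statistical verification of an FNN-selected characteristic:
# maximum-likelihood logistic odds ratios under four nested adjustment
# models, signed correlation ratios (point-biserial) between biomarkers
# and lifestyle habits, and baseline-characteristic group comparisons
# (pooled t test / Pearson chi-square without continuity correction).

# adjustment-set ladder; model 4 (exercise) applies where exercise exists
or_adjustment_sets <- function(model_id) {
  switch(as.character(model_id),
         "1" = character(0),
         "2" = c("age", "alcohol", "smoking"),
         "3" = c("age", "alcohol", "smoking",
                 "bmi", "sbp", "dbp", "tg", "hdl", "glucose"),
         "4" = c("age", "alcohol", "smoking",
                 "bmi", "sbp", "dbp", "tg", "hdl", "glucose", "exercise"),
         stop("model_id must be 1, 2, 3 or 4"))
}

#' Adjusted logistic odds ratio for a predictor
#'
#' Maximum-likelihood logistic regression of case (vs healthy control)
#' status on the predictor plus a nested adjustment set:
#' \describe{
#'   \item{model 1}{unadjusted;}
#'   \item{model 2}{+ age, drinking habit, smoking habit;}
#'   \item{model 3}{model 2 + the MetS components (BMI, SBP, DBP,
#'     triglycerides, HDL, fasting glucose);}
#'   \item{model 4}{model 3 + exercise habit.}
#' }
#' With `transform = "doubling"` the predictor enters as log2, so the OR
#' is per doubling of the raw value. Confidence intervals and p-values are
#' Wald. Perfect separation triggers a ridge-penalized fallback, flagged.
#'
#' @param data Labeled analysis table (`target` +1/-1 or `label` column),
#'   e.g. from [analysis_table()].
#' @param predictor Predictor column name.
#' @param transform `"identity"` or `"doubling"` (log2).
#' @param model_id Adjustment model, 1-4.
#' @param extra Optional extra covariate names (e.g. a study indicator for
#'   pooled analyses).
#' @return A list of class `adjusted_or`: `predictor`, `transform`,
#'   `model_id`, `or`, `ci_low`, `ci_high`, `p`, `n`, `penalized`.
#' @export
logistic_or <- function(data, predictor, transform = c("identity", "doubling"),
                        model_id = 1, extra = character(0)) {
  transform <- match.arg(transform)
  if (!"target" %in% names(data)) data <- analysis_table(data)
  adj <- c(or_adjustment_sets(model_id), extra)
  adj <- adj[adj %in% names(data)]
  need <- c(predictor, adj)
  d <- complete_case_subset(data, need)
  if (transform == "doubling") {
    if (any(d[[predictor]] <= 0))
      stop("doubling transform requires a strictly positive predictor")
    d$.x <- log2(d[[predictor]])
  } else d$.x <- d[[predictor]]
  d$.y <- as.integer(d$target == 1)
  if (length(unique(d$.y)) < 2) stop("both outcome classes required")

  fml <- stats::reformulate(c(".x", adj), response = ".y")
  fit <- suppressWarnings(stats::glm(fml, data = d, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  co <- summary(fit)$coefficients
  penalized <- FALSE
  if (!fit$converged || !".x" %in% rownames(co) ||
      abs(co[".x", "Estimate"]) > 15) {
    penalized <- TRUE
    mm <- stats::model.matrix(fml, d)[, -1, drop = FALSE]
    if (ncol(mm) == 1) mm <- cbind(mm, 0)
    fit2 <- glmnet::glmnet(mm, d$.y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
    est <- stats::coef(fit2)[".x", 1]
    se <- NA_real_; p <- NA_real_
  } else {
    est <- co[".x", "Estimate"]
    se <- co[".x", "Std. Error"]
    p <- co[".x", "Pr(>|z|)"]
  }
  structure(list(predictor = predictor, transform = transform,
                 model_id = model_id,
                 or = exp(est),
                 ci_low = exp(est - stats::qnorm(0.975) * se),
                 ci_high = exp(est + stats::qnorm(0.975) * se),
                 p = p, n = nrow(d), penalized = penalized),
            class = "adjusted_or")
}

#' @export
print.adjusted_or <- function(x, ...) {
  cat(sprintf("%s (%s), model %s: OR %.2f (%.2f-%.2f), p = %.3g, n = %d%s\n",
              x$predictor, x$transform, x$model_id, x$or, x$ci_low, x$ci_high,
              x$p, x$n, if (x$penalized) " [penalized]" else ""))
  invisible(x)
}

#' Signed correlation ratio (point-biserial) with a binary characteristic
#'
#' For a binary grouping the correlation ratio eta (between-group over
#' total variance, square-rooted) equals in magnitude the Pearson
#' correlation of the continuous variable with the 0/1 indicator; the sign
#' is kept (positive when the habit-present group has the higher mean).
#' The p-value is the exact t transform with n - 2 degrees of freedom.
#'
#' @param values Continuous vector.
#' @param group Binary vector (0/1 or logical).
#' @return A list of class `correlation_eta`: `eta`, `p`, `n`,
#'   `mean_present`, `mean_absent`.
#' @export
#' @examples
#' correlation_eta(c(1, 2, 3, 4), c(0, 0, 1, 1))$eta  # 0.8944
correlation_eta <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.numeric(group[keep])
  if (!all(group %in% c(0, 1))) stop("group must be binary 0/1")
  if (length(unique(group)) < 2) stop("both groups must be nonempty")
  if (stats::sd(values) == 0) stop("continuous values are constant")
  n <- length(values)
  eta <- stats::cor(values, group)
  tt <- eta * sqrt((n - 2) / (1 - eta^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(list(eta = eta, p = p, n = n,
                 mean_present = mean(values[group == 1]),
                 mean_absent = mean(values[group == 0])),
            class = "correlation_eta")
}

#' @export
print.correlation_eta <- function(x, ...) {
  cat(sprintf("eta = %.3f (n = %d, p = %.3g)\n", x$eta, x$n, x$p))
  invisible(x)
}

#' Two-group comparison of a baseline characteristic
#'
#' Continuous characteristics: two-sample t test (pooled-variance Student
#' by default; `welch = TRUE` for the unequal-variance test). Categorical
#' characteristics: Pearson chi-square on the 2x2 table without continuity
#' correction.
#'
#' @param x,y For `type = "continuous"`: the two groups' values. For
#'   `type = "categorical"`: vectors `c(successes, size)` per group.
#' @param type `"continuous"` or `"categorical"`.
#' @param welch Use Welch's t test instead of pooled-variance Student.
#' @return A list: `p`, plus `mean`/`sd` per group (continuous) or
#'   `n`/`pct` per group (categorical).
#' @export
#' @examples
#' group_compare(c(51, 75), c(81, 151), type = "categorical")$p  # ~0.0392
group_compare <- function(x, y, type = c("continuous", "categorical"),
                          welch = FALSE) {
  type <- match.arg(type)
  if (type == "continuous") {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) stop("both groups must be nonempty")
    tt <- stats::t.test(x, y, var.equal = !welch)
    list(p = tt$p.value, type = type,
         n = c(length(x), length(y)),
         mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)))
  } else {
    if (length(x) != 2 || length(y) != 2)
      stop("categorical groups are c(successes, size)")
    tab <- rbind(c(x[1], x[2] - x[1]), c(y[1], y[2] - y[1]))
    if (any(tab < 0)) stop("successes cannot exceed group size")
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    list(p = p, type = type, n = c(x[1], y[1]),
         pct = c(100 * x[1] / x[2], 100 * y[1] / y[2]))
  }
}

#' Baseline characteristics table with group comparisons
#'
#' One row per characteristic: complete-case n per group, mean +/- SD (or
#' n and percent for binary characteristics), and the [group_compare()]
#' p-value, comparing cases with healthy controls.
#'
#' @param cohort Labeled `mets_cohort` or baseline data frame with `label`.
#' @param characteristics Columns to summarize (default: a standard panel).
#' @return Data frame, one row per characteristic.
#' @export
characteristics_table <- function(cohort,
                                  characteristics = c("age", "height",
                                                      "weight", "bmi", "sbp",
                                                      "dbp", "tc", "tg",
                                                      "hdl", "glucose",
                                                      "alcohol", "smoking")) {
  b <- if (inherits(cohort, "mets_cohort")) cohort$baseline else cohort
  if (nrow(b) == 0)
    return(data.frame(characteristic = character(0), n_case = integer(0),
                      case_summary = character(0), n_control = integer(0),
                      control_summary = character(0), p = numeric(0)))
  ca <- b[b$label == "case", , drop = FALSE]
  co <- b[b$label == "healthy_control", , drop = FALSE]
  rows <- lapply(intersect(characteristics, names(b)), function(ch) {
    xc <- ca[[ch]]; xh <- co[[ch]]
    binary <- all(stats::na.omit(c(xc, xh)) %in% c(0, 1))
    if (binary) {
      nc <- sum(!is.na(xc)); nh <- sum(!is.na(xh))
      gc_ <- group_compare(c(sum(xc, na.rm = TRUE), nc),
                           c(sum(xh, na.rm = TRUE), nh), "categorical")
      data.frame(characteristic = ch, n_case = nc,
                 case_summary = sprintf("%d (%.1f%%)", gc_$n[1], gc_$pct[1]),
                 n_control = nh,
                 control_summary = sprintf("%d (%.1f%%)", gc_$n[2], gc_$pct[2]),
                 p = gc_$p, stringsAsFactors = FALSE)
    } else {
      gc_ <- group_compare(xc, xh, "continuous")
      data.frame(characteristic = ch, n_case = gc_$n[1],
                 case_summary = sprintf("%.1f ± %.1f", gc_$mean[1], gc_$sd[1]),
                 n_control = gc_$n[2],
                 control_summary = sprintf("%.1f ± %.1f", gc_$mean[2], gc_$sd[2]),
                 p = gc_$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Habit-biomarker correlation-ratio table
#'
#' Signed correlation ratios of selected continuous characteristics with
#' the binary lifestyle habits, over all labeled (non-excluded) subjects.
#'
#' @param cohort Labeled cohort or baseline data frame.
#' @param continuous Continuous characteristic columns (default gamma-GTP
#'   and WBC).
#' @param habits Binary habit columns (default alcohol and smoking).
#' @return Data frame: characteristic, habit, n, eta, p.
#' @export
eta_table <- function(cohort, continuous = c("ggt", "wbc"),
                      habits = c("alcohol", "smoking")) {
  b <- if (inherits(cohort, "mets_cohort")) cohort$baseline else cohort
  if ("label" %in% names(b)) b <- b[b$label != "excluded", , drop = FALSE]
  rows <- list()
  for (ch in continuous) for (h in habits) {
    r <- correlation_eta(b[[ch]], b[[h]])
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = ch, habit = h, n = r$n, eta = r$eta, p = r$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
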