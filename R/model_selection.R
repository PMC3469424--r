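# Five-fold cross-validation, the weighted accuracy that scores training
# and validation correctness 1:2, the null-method (majority-class)
# baseline, greedy parameter-increasing forward selection over the
# candidate inputs, and multiple linear / logistic regression comparators.

#' Weighted training/validation accuracy
#'
#' `100 * [ (correct_train / n_train) * 1/3 + (correct_test / n_test) * 2/3 ]`
#' — validation correctness carries twice the weight of training
#' correctness.
#'
#' @param correct_train,n_train Correct estimations and size, training set.
#' @param correct_test,n_test Correct estimations and size, validation set.
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
#' @examples
#' weighted_accuracy(80, 100, 40, 80)  # 60
weighted_accuracy <- function(correct_train, n_train, correct_test, n_test) {
  if (n_train <= 0 || n_test <= 0) stop("set sizes must be positive")
  if (correct_train < 0 || correct_train > n_train ||
      correct_test < 0 || correct_test > n_test)
    stop("correct counts must lie in [0, n]")
  100 * (correct_train / n_train / 3 + correct_test / n_test * 2 / 3)
}

#' Null-method baseline accuracy
#'
#' Accuracy of the null method that estimates every subject to belong to
#' the majority class.
#'
#' @param n_case,n_control Class sizes.
#' @return Percent, rounded to 2 decimals for reporting.
#' @export
#' @examples
#' null_baseline(57, 99)   # 63.46
#' null_baseline(45, 79)   # 63.71
null_baseline <- function(n_case, n_control) {
  if (n_case + n_control <= 0) stop("need at least one subject")
  round(100 * max(n_case, n_control) / (n_case + n_control), 2)
}

#' Seeded five-fold cross-validation plan
#'
#' Subjects are randomly arranged (seeded shuffle) and divided into
#' `folds` contiguous near-equal folds (sizes differ by at most one).
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param folds Number of folds (default 5).
#' @param strata Optional class vector of length `n`; when given, the
#'   shuffle-and-deal happens within each class so every fold carries a
#'   near-proportional share of cases and controls. The default plan used
#'   by [forward_select()] stratifies on the target, which keeps the
#'   per-fold accuracy comparable across candidate input sets at the small
#'   n left after complete-case filtering.
#' @return A list of class `cv_plan`: `$order` (the shuffle) and `$fold`
#'   (fold id per subject, aligned with the original row order).
#' @export
make_cv_plan <- function(n, seed, folds = 5L, strata = NULL) {
  if (n < folds) stop("need at least ", folds, " subjects for ", folds,
                      "-fold cross-validation")
  set.seed(seed)
  ord <- sample.int(n)
  if (is.null(strata)) {
    sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds),
                                         rep(0L, folds - n %% folds))
    fold_of_pos <- rep(seq_len(folds), times = sizes)
    fold <- integer(n)
    fold[ord] <- fold_of_pos
  } else {
    if (length(strata) != n) stop("strata must have length n")
    fold <- integer(n)
    for (cl in unique(strata[ord])) {
      idx <- ord[strata[ord] == cl]       # class members in shuffled order
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    # rebalance fold sizes to differ by at most one overall
    repeat {
      sz <- tabulate(fold, folds)
      if (max(sz) - min(sz) <= 1L) break
      from <- which.max(sz); to <- which.min(sz)
      move <- which(fold == from)[1L]
      fold[move] <- to
    }
  }
  structure(list(order = ord, fold = fold, folds = folds, seed = seed,
                 stratified = !is.null(strata)),
            class = "cv_plan")
}

#' Cross-validated FNN accuracy
#'
#' For each fold: train on the other folds, count correct estimations
#' (`y* > 0` case, `y* < 0` control, ties never correct) on both the
#' training and the held-out set, and score with [weighted_accuracy()].
#' The returned accuracy is the mean of the per-fold values.
#'
#' @param data Complete-case data frame with input columns and `target`.
#' @param inputs Input column names.
#' @param plan A [make_cv_plan()] for `nrow(data)` subjects.
#' @param config An [fnn_config()] passed to [fnn_train()].
#' @return Numeric accuracy (percent) with attribute `"per_fold"`.
#' @export
cv_accuracy <- function(data, inputs, plan, config = fnn_config()) {
  fold_acc <- vapply(seq_len(plan$folds), function(f) {
    tr <- data[plan$fold != f, , drop = FALSE]
    te <- data[plan$fold == f, , drop = FALSE]
    if (length(unique(tr$target)) < 2 || nrow(te) == 0)
      stop("fold ", f, " lacks both classes; use a larger or stratified plan")
    model <- fnn_train(tr, inputs, config)
    weighted_accuracy(n_correct(fnn_predict(model, tr), tr$target), nrow(tr),
                      n_correct(fnn_predict(model, te), te$target), nrow(te))
  }, numeric(1))
  structure(mean(fold_acc), per_fold = fold_acc)
}

#' Cross-validated comparator accuracy (linear or logistic regression)
#'
#' Fits multiple linear regression on the +1/-1 targets (case iff fitted
#' value > 0) or multiple logistic regression (case iff fitted probability
#' > 0.5), on the same complete-case subset and the same CV plan as the
#' FNN, scored with the identical weighted accuracy. Perfect separation in
#' the logistic fit triggers a ridge-penalized fallback, flagged in the
#' `"penalized"` attribute.
#'
#' @inheritParams cv_accuracy
#' @param kind `"linear"` or `"logistic"`.
#' @return Numeric accuracy (percent); attributes `"per_fold"`,
#'   `"penalized"`.
#' @export
comparator_accuracy <- function(data, inputs, plan, kind = c("linear", "logistic")) {
  kind <- match.arg(kind)
  penalized <- FALSE
  fold_acc <- vapply(seq_len(plan$folds), function(f) {
    tr <- data[plan$fold != f, , drop = FALSE]
    te <- data[plan$fold == f, , drop = FALSE]
    fml <- if (length(inputs))
      stats::reformulate(inputs, response = "target") else target ~ 1
    if (kind == "linear") {
      fit <- stats::lm(fml, data = tr)
      sc_tr <- stats::predict(fit, tr)
      sc_te <- stats::predict(fit, te)
    } else {
      tr$target01 <- (tr$target + 1) / 2
      fml01 <- if (length(inputs))
        stats::reformulate(inputs, response = "target01") else target01 ~ 1
      fit <- suppressWarnings(stats::glm(fml01, data = tr, family = stats::binomial()))
      sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
      if (is.na(sep)) sep <- TRUE
      if (sep && length(inputs) >= 1) {
        penalized <<- TRUE
        Xtr <- as.matrix(tr[, inputs, drop = FALSE])
        Xte <- as.matrix(te[, inputs, drop = FALSE])
        if (ncol(Xtr) == 1) { Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0) }
        fit2 <- glmnet::glmnet(Xtr, tr$target01, family = "binomial",
                               alpha = 0, lambda = 1e-3)
        sc_tr <- as.numeric(stats::predict(fit2, Xtr, type = "response")) - 0.5
        sc_te <- as.numeric(stats::predict(fit2, Xte, type = "response")) - 0.5
      } else {
        sc_tr <- stats::predict(fit, tr, type = "response") - 0.5
        sc_te <- stats::predict(fit, te, type = "response") - 0.5
      }
    }
    weighted_accuracy(n_correct(sc_tr, tr$target), nrow(tr),
                      n_correct(sc_te, te$target), nrow(te))
  }, numeric(1))
  structure(mean(fold_acc), per_fold = fold_acc, penalized = penalized)
}

# complete-case analysis subset for a given input set
complete_case_subset <- function(data, inputs) {
  keep <- stats::complete.cases(data[, inputs, drop = FALSE])
  data[keep, , drop = FALSE]
}

# evaluate one input set: complete-case counts, baseline, FNN and
# comparator CV accuracies, all on the same seeded plan
evaluate_input_set <- function(data, inputs, seed, folds = 5L,
                               config = fnn_config(), comparators = TRUE,
                               stratify = TRUE) {
  d <- complete_case_subset(data, inputs)
  n_case <- sum(d$target == 1); n_control <- sum(d$target == -1)
  if (n_case < 2 || n_control < 2 || nrow(d) < folds)
    return(NULL)
  plan <- make_cv_plan(nrow(d), seed = seed, folds = folds,
                       strata = if (stratify) d$target)
  acc <- tryCatch(cv_accuracy(d, inputs, plan, config),
                  error = function(e) NA_real_)
  res <- list(inputs = inputs, n_case = n_case, n_control = n_control,
              baseline = null_baseline(n_case, n_control),
              fnn = as.numeric(acc),
              fnn_per_fold = attr(acc, "per_fold"))
  if (comparators && !is.na(res$fnn)) {
    res$linear <- as.numeric(comparator_accuracy(d, inputs, plan, "linear"))
    res$logistic <- as.numeric(comparator_accuracy(d, inputs, plan, "logistic"))
  } else {
    res$linear <- NA_real_; res$logistic <- NA_real_
  }
  res
}

#' Parameter-increasing (forward) input selection
#'
#' Stage 1 evaluates every candidate alone by cross-validated FNN accuracy
#' and keeps the best; stage 2 pairs the stage-1 winner with each
#' remaining candidate and keeps the best pair; and so on up to `k_max`
#' inputs. Every stage re-derives the complete-case subset for its own
#' input set, so the analysis n varies between stages. Ties are broken
#' toward the earlier candidate (lower input number).
#'
#' @param data Labeled analysis table (see [analysis_table()]): input
#'   columns plus a `target` column coded +1/-1.
#' @param candidates Character vector of candidate inputs, in input-number
#'   order (default [candidate_inputs()]).
#' @param k_max Maximum number of inputs (default 2).
#' @param seed Seed for the CV plans (one shared seed; every candidate at
#'   a given subset size sees the same plan when their complete-case
#'   subsets coincide).
#' @param folds Number of CV folds (default 5).
#' @param config An [fnn_config()].
#' @param stratify Stratify CV folds by class (default `TRUE`); see
#'   [make_cv_plan()].
#' @return A list of class `selection_result`: `$stages` — a data frame
#'   with one row per stage (inputs, n_case, n_control, baseline, FNN,
#'   linear, logistic accuracies) shaped like a model-comparison table —
#'   and `$trace` — per-stage accuracy of every evaluated candidate set.
#' @export
forward_select <- function(data, candidates = candidate_inputs(), k_max = 2L,
                           seed = 1L, folds = 5L, config = fnn_config(),
                           stratify = TRUE) {
  candidates <- candidates[candidates %in% names(data)]
  if (!length(candidates)) stop("no usable candidates")
  selected <- character(0)
  stages <- list(); trace <- list()

  for (stage in seq_len(k_max)) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    evals <- lapply(remaining, function(cand)
      evaluate_input_set(data, c(selected, cand), seed = seed, folds = folds,
                         config = config, comparators = FALSE,
                         stratify = stratify))
    names(evals) <- remaining
    ok <- !vapply(evals, is.null, logical(1))
    ok[ok] <- !is.na(vapply(evals[ok], `[[`, numeric(1), "fnn"))
    if (!any(ok)) {
      if (stage == 1) stop("all candidates degenerate")
      break
    }
    accs <- vapply(evals[ok], `[[`, numeric(1), "fnn")
    best_cand <- names(accs)[which.max(accs)]  # first max = lowest index
    selected <- c(selected, best_cand)

    # winner re-evaluated with comparators on its own subset/plan
    win <- evaluate_input_set(data, selected, seed = seed, folds = folds,
                              config = config, comparators = TRUE,
                              stratify = stratify)
    stages[[stage]] <- data.frame(
      stage = stage, inputs = paste(selected, collapse = "+"),
      n_case = win$n_case, n_control = win$n_control,
      baseline = win$baseline, fnn = win$fnn,
      linear = win$linear, logistic = win$logistic,
      stringsAsFactors = FALSE)
    trace[[stage]] <- data.frame(
      stage = stage, candidate = names(accs),
      inputs = vapply(evals[ok], function(e) paste(e$inputs, collapse = "+"),
                      character(1)),
      n_case = vapply(evals[ok], `[[`, numeric(1), "n_case"),
      n_control = vapply(evals[ok], `[[`, numeric(1), "n_control"),
      fnn = accs, stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(stages = do.call(rbind, stages),
                 trace = do.call(rbind, trace),
                 selected = selected, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> selected:", paste(x$selected, collapse = " + "), "\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
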