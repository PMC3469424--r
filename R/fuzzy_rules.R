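# Fuzzy-rule extraction from a trained FNN: per-input low/high crossover
# thresholds in raw units, crisp low/high cell assignment, 2x2 (or 2^k)
# cell counts of cases and controls with the rule weights Wf, and scatter
# data export for the selected input pair.

#' Low/high crossover threshold of an input, in raw units
#'
#' The raw value at which the "high" membership function crosses grade
#' 0.5: standardized `x* = Wc_high / Wg_high`, mapped back through the
#' model's stored mean and sd (and the log transform, if the input was
#' log-transformed for training).
#'
#' @param model A trained `fnn_model`.
#' @param input Input name (default: all model inputs).
#' @return Named numeric vector of thresholds.
#' @export
crossover_threshold <- function(model, input = model$inputs) {
  vapply(input, function(j) {
    wg <- model$Wg["high", j]
    if (wg == 0) stop("flat high membership for ", j, ": no crossover")
    z <- model$Wc["high", j] / wg
    raw <- model$center[j] + model$scale[j] * z
    if (j %in% (model$log_inputs %||% character(0))) raw <- exp(raw)
    unname(raw)
  }, numeric(1))
}

#' Assign subjects to low/high rule cells
#'
#' Crisp assignment: an input is "high" when the raw value is at or above
#' its crossover threshold (boundary inclusive), "low" below it. With
#' `method = "membership"` the fuzzy assignment (argmax of f_low vs
#' f_high) is used instead.
#'
#' @param model A trained `fnn_model`.
#' @param data Complete-case data frame with the model inputs.
#' @param method `"threshold"` (default) or `"membership"`.
#' @return Character vector of cell labels such as `"high.low"` (levels
#'   ordered as the model's inputs).
#' @export
assign_cell <- function(model, data, method = c("threshold", "membership")) {
  method <- match.arg(method)
  X <- data[, model$inputs, drop = FALSE]
  if (anyNA(X)) stop("assign_cell requires complete-case rows")
  if (method == "threshold") {
    thr <- crossover_threshold(model)
    lv <- vapply(model$inputs, function(j)
      ifelse(X[[j]] >= thr[j], "high", "low"), character(nrow(X)))
  } else {
    for (li in model$log_inputs %||% character(0)) X[[li]] <- log(X[[li]])
    Z <- standardize_inputs(model, X)
    grades <- grade_matrices(model, Z)
    lv <- vapply(seq_along(model$inputs), function(j)
      ifelse(grades[[j]][, "high"] >= grades[[j]][, "low"], "high", "low"),
      character(nrow(X)))
  }
  lv <- matrix(lv, nrow = nrow(X))
  apply(lv, 1, paste, collapse = ".")
}

#' Build the fuzzy rule matrix
#'
#' For every low/high cell combination: the number of case and healthy
#' control subjects assigned to the cell and the rule weight `Wf` of the
#' corresponding production rule. Cell counts always sum to the
#' complete-case class totals.
#'
#' @param model A trained `fnn_model`.
#' @param data Labeled complete-case analysis table (with `target`).
#' @param method Cell assignment method, see [assign_cell()].
#' @return A list of class `fuzzy_rule_matrix`: `$thresholds` (raw-unit
#'   crossovers), `$cells` (data frame: cell, per-input level, n_case,
#'   n_control, Wf), `$inputs`.
#' @export
build_rule_matrix <- function(model, data, method = "threshold") {
  cells <- assign_cell(model, data, method)
  all_cells <- rule_names(model$rules)
  tab <- data.frame(cell = all_cells, stringsAsFactors = FALSE)
  lv <- strsplit(all_cells, ".", fixed = TRUE)
  for (j in seq_along(model$inputs))
    tab[[model$inputs[j]]] <- vapply(lv, `[[`, character(1), j)
  tab$n_case <- vapply(all_cells, function(cl)
    sum(cells == cl & data$target == 1), numeric(1))
  tab$n_control <- vapply(all_cells, function(cl)
    sum(cells == cl & data$target == -1), numeric(1))
  tab$Wf <- as.numeric(model$Wf[all_cells])
  rownames(tab) <- NULL
  structure(list(thresholds = crossover_threshold(model), cells = tab,
                 inputs = model$inputs),
            class = "fuzzy_rule_matrix")
}

#' @export
print.fuzzy_rule_matrix <- function(x, ...) {
  cat("<fuzzy_rule_matrix>", paste(x$inputs, collapse = " x "), "\n")
  cat("thresholds:",
      paste(sprintf("%s >= %.3g", x$inputs, x$thresholds), collapse = ", "),
      "\n")
  for (i in seq_len(nrow(x$cells))) {
    r <- x$cells[i, ]
    cat(sprintf("  [%s]  case/control: %d/%d   Wf = %.3f\n", r$cell,
                as.integer(r$n_case), as.integer(r$n_control), r$Wf))
  }
  invisible(x)
}

#' Export rule matrix as JSON
#'
#' @param rule A `fuzzy_rule_matrix`.
#' @param path Output path.
#' @export
rule_matrix_to_json <- function(rule, path) {
  jsonlite::write_json(list(inputs = rule$inputs,
                            thresholds = as.list(rule$thresholds),
                            cells = rule$cells),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export scatter data for a selected input pair
#'
#' Plain plotting table (no figure styling): one row per complete-case
#' subject with the two input values and the cohort label.
#'
#' @param data Labeled analysis table.
#' @param inputs Character vector (typically 2) of input columns.
#' @return Data frame with the input columns and `label`.
#' @export
export_scatter <- function(data, inputs) {
  d <- complete_case_subset(data, inputs)
  lab <- if ("label" %in% names(d)) d$label
         else ifelse(d$target > 0, "case", "healthy_control")
  out <- d[, inputs, drop = FALSE]
  out$label <- lab
  rownames(out) <- NULL
  out
}
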