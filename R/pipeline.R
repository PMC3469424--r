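# End-to-end pipeline: simulate -> label -> select -> rules -> verify ->
# report, plus CSV round-trip I/O and YAML/JSON configuration. One global
# seed is fanned out as stage_seed = seed * 8 + stage_index (simulate = 0,
# selection = 3), so stages can be rerun independently yet reproducibly.

stage_seed <- function(seed, stage) as.integer(seed) * 8L + as.integer(stage)

#' Write / read a cohort baseline table as CSV
#'
#' UTF-8 CSV with empty fields for missing values; lossless round-trip of
#' values, labels and missingness.
#'
#' @param data Baseline data frame (possibly labeled).
#' @param path File path.
#' @export
write_cohort_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param expected_numeric Optional column names that must parse as
#'   numeric; a malformed entry raises an error naming row and column.
#' @export
read_cohort_csv <- function(path, expected_numeric = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (is.null(expected_numeric))
    expected_numeric <- setdiff(names(df), c("label", "exercise"))
  for (cl in intersect(expected_numeric, names(df))) {
    v <- df[[cl]]
    if (is.numeric(v)) next
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad))
      stop("non-numeric value in column '", cl, "', row ", bad[1],
           ": '", v[bad[1]], "'")
    df[[cl]] <- parsed
  }
  df
}

#' Pipeline configuration
#'
#' @param spec A [cohort_spec()] (or arguments for one via `preset`,
#'   `n_subjects`).
#' @param seed Global seed, fanned out to the stages.
#' @param candidates Candidate inputs for selection.
#' @param k_max,folds Selection settings.
#' @param or_models Adjustment models to fit (subset of 1:4).
#' @param out_dir Output directory for stage artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), seed = 1L,
                            candidates = candidate_inputs(), k_max = 2L,
                            folds = 5L, or_models = c(1, 2, 3),
                            out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  structure(list(spec = spec, seed = as.integer(seed),
                 candidates = candidates, k_max = k_max, folds = folds,
                 or_models = or_models, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may carry any [pipeline_config()] field; `spec` is a mapping
#' of [cohort_spec()] overrides (`preset`, `n_subjects`,
#' `follow_up_years`, plus any spec field).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  sp <- raw$spec %||% list()
  spec_args <- c(list(preset = sp$preset %||% "original",
                      n_subjects = sp$n_subjects,
                      follow_up_years = sp$follow_up_years %||% 8L,
                      seed = sp$seed %||% raw$seed %||% 1L),
                 sp[setdiff(names(sp),
                            c("preset", "n_subjects", "follow_up_years",
                              "seed"))])
  spec <- do.call(cohort_spec, spec_args)
  pipeline_config(spec = spec,
                  seed = raw$seed %||% 1L,
                  candidates = raw$candidates %||% candidate_inputs(),
                  k_max = raw$k_max %||% 2L,
                  folds = raw$folds %||% 5L,
                  or_models = raw$or_models %||% c(1, 2, 3),
                  out_dir = raw$out_dir)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> label -> select -> rules -> verify and assembles a
#' machine-readable summary. Rerunning with the same configuration yields
#' identical results; when `out_dir` is set, stage outputs are written as
#' CSV/JSON.
#'
#' @param config A [pipeline_config()] (or a path readable by
#'   [read_pipeline_config()]).
#' @param quiet Suppress stage logging.
#' @return A list of class `pipeline_result`: `$cohort`, `$selection`,
#'   `$rule_matrix`, `$or_table`, `$eta_table`, `$characteristics`,
#'   `$summary` (plain list, JSON-serializable).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- if (quiet) function(...) invisible(NULL) else log_stage

  spec <- config$spec
  spec$seed <- stage_seed(config$seed, 0L)
  say("simulate", sprintf("n=%d preset=%s seed=%d", spec$n_subjects,
                          spec$preset, spec$seed))
  cohort <- generate_cohort(spec)

  say("label", sprintf("labels: %s",
                       paste(names(table(cohort$baseline$label)),
                             table(cohort$baseline$label),
                             sep = "=", collapse = " ")))
  ana <- analysis_table(cohort)
  if (nrow(ana) < config$folds)
    stop("stage 'label': too few case/healthy-control subjects (",
         nrow(ana), ") for ", config$folds, "-fold cross-validation")

  sel_seed <- stage_seed(config$seed, 3L)
  say("select", sprintf("%d candidates, k_max=%d, seed=%d",
                        length(config$candidates), config$k_max, sel_seed))
  sel <- tryCatch(
    forward_select(ana, candidates = config$candidates,
                   k_max = config$k_max, seed = sel_seed,
                   folds = config$folds,
                   config = fnn_config(seed = sel_seed)),
    error = function(e) stop("stage 'select': ", conditionMessage(e),
                             call. = FALSE))
  say("select", "selected:", paste(sel$selected, collapse = " + "))

  say("rules", "refitting on the full complete-case subset")
  d_sel <- complete_case_subset(ana, sel$selected)
  final_model <- fnn_train(d_sel, sel$selected,
                           fnn_config(seed = sel_seed))
  rule <- build_rule_matrix(final_model, d_sel)
  scatter <- export_scatter(ana, sel$selected)

  say("verify", "adjusted ORs and correlation ratios")
  or_rows <- list()
  for (pr in sel$selected) for (mid in config$or_models) {
    tr <- if (pr == "ggt") "doubling" else "identity"
    res <- tryCatch(logistic_or(ana, pr, transform = tr, model_id = mid),
                    error = function(e) NULL)
    if (!is.null(res))
      or_rows[[length(or_rows) + 1]] <- data.frame(
        predictor = pr, transform = tr, model = mid, or = res$or,
        ci_low = res$ci_low, ci_high = res$ci_high, p = res$p, n = res$n,
        penalized = res$penalized, stringsAsFactors = FALSE)
  }
  or_table <- if (length(or_rows)) do.call(rbind, or_rows) else NULL
  etas <- eta_table(cohort)
  chars <- characteristics_table(cohort)

  summary <- list(
    seed = config$seed,
    preset = spec$preset,
    n_subjects = nrow(cohort$baseline),
    labels = as.list(table(cohort$baseline$label)),
    selected = sel$selected,
    stages = sel$stages,
    thresholds = as.list(rule$thresholds),
    rule_cells = rule$cells,
    or_table = or_table,
    eta_table = etas
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_cohort_csv(cohort$baseline, file.path(od, "baseline_labeled.csv"))
    write_cohort_csv(cohort$followup, file.path(od, "followup.csv"))
    utils::write.csv(sel$stages, file.path(od, "selection.csv"),
                     row.names = FALSE)
    rule_matrix_to_json(rule, file.path(od, "rule_matrix.json"))
    write_cohort_csv(scatter, file.path(od, "scatter.csv"))
    if (!is.null(or_table))
      utils::write.csv(or_table, file.path(od, "odds_ratios.csv"),
                       row.names = FALSE)
    utils::write.csv(etas, file.path(od, "correlation_ratios.csv"),
                     row.names = FALSE)
    utils::write.csv(chars, file.path(od, "characteristics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    say("report", "written to ", od)
  }

  structure(list(cohort = cohort, selection = sel, model = final_model,
                 rule_matrix = rule, scatter = scatter, or_table = or_table,
                 eta_table = etas, characteristics = chars,
                 summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$selection)
  print(x$rule_matrix)
  invisible(x)
}
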