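# Fuzzy neural network core: each input feeds two sigmoid membership
# functions ("low", non-increasing; "high", non-decreasing); product units
# combine one membership per input into 2^k rule activations; the output
# y* is the weighted sum of rule activations with rule weights Wf.
# Classification convention: y* > 0 estimates a case, y* < 0 a healthy
# control, and y* = 0 is never counted as correct for either class.

#' Sigmoid membership grade
#'
#' Grade of membership `f(x) = 1 / (1 + exp(-Wg * x + Wc))` of a
#' standardized input `x`. `Wg` sets the gradient (its sign makes the
#' function a "high" or a "low" membership), `Wc` the position: the grade
#' crosses 0.5 at `x = Wc / Wg`.
#'
#' @param x Standardized input value(s); must be finite.
#' @param Wc Center weight.
#' @param Wg Gradient weight.
#' @return Grades in (0, 1), same length as `x`.
#' @export
#' @examples
#' membership(0, Wc = 1, Wg = 2)  # 1 / (1 + e) = 0.2689414
membership <- function(x, Wc, Wg) {
  if (!all(is.finite(x)) || !is.finite(Wc) || !is.finite(Wg))
    stop("membership() requires finite arguments")
  stats::plogis(Wg * x - Wc)
}

# rule index table: 2^k rows, entries 1 = low, 2 = high; all combinations
rule_table <- function(k) {
  m <- as.matrix(expand.grid(rep(list(c(1L, 2L)), k)))
  dimnames(m) <- NULL
  m
}

rule_names <- function(rules) {
  lv <- c("low", "high")
  apply(rules, 1, function(r) paste(lv[r], collapse = "."))
}

#' Construct an (untrained) FNN model
#'
#' Membership functions start symmetric around the standardized median:
#' `f_high` with `Wg = +2, Wc = 0`, `f_low` mirrored with `Wg = -2,
#' Wc = 0`; all rule weights `Wf` start at 0 (a null model).
#'
#' @param inputs Character vector of input column names (k of them).
#' @param center,scale Named standardization constants (training mean/sd).
#' @return An object of class `fnn_model`.
#' @export
fnn_model <- function(inputs, center, scale) {
  k <- length(inputs)
  if (k < 1) stop("at least one input required")
  if (any(scale <= 0)) stop("standardization sds must be positive")
  rules <- rule_table(k)
  structure(list(
    inputs = inputs,
    center = stats::setNames(as.numeric(center[inputs]), inputs),
    scale = stats::setNames(as.numeric(scale[inputs]), inputs),
    Wc = matrix(0, 2, k, dimnames = list(c("low", "high"), inputs)),
    Wg = matrix(rep(c(-2, 2), k), 2, k,
                dimnames = list(c("low", "high"), inputs)),
    Wf = stats::setNames(numeric(nrow(rules)), rule_names(rules)),
    rules = rules,
    loss = numeric(0)
  ), class = "fnn_model")
}

#' @export
print.fnn_model <- function(x, ...) {
  cat("<fnn_model> inputs:", paste(x$inputs, collapse = " x "), "\n")
  cat("  rule weights Wf:\n")
  print(round(x$Wf, 4))
  invisible(x)
}

# standardize the model's inputs out of a data frame; errors on NA
standardize_inputs <- function(model, data) {
  X <- as.matrix(data[, model$inputs, drop = FALSE])
  if (anyNA(X))
    stop("missing input values; complete-case filtering must happen upstream")
  storage.mode(X) <- "double"
  sweep(sweep(X, 2, model$center), 2, model$scale, "/")
}

# membership grades for standardized X: list over inputs of n x 2 matrices
grade_matrices <- function(model, Z) {
  lapply(seq_along(model$inputs), function(j) {
    cbind(low = stats::plogis(model$Wg["low", j] * Z[, j] - model$Wc["low", j]),
          high = stats::plogis(model$Wg["high", j] * Z[, j] - model$Wc["high", j]))
  })
}

# rule activations Pi: n x 2^k
rule_activations <- function(model, grades) {
  n <- nrow(grades[[1]])
  act <- matrix(1, n, nrow(model$rules))
  for (r in seq_len(nrow(model$rules)))
    for (j in seq_along(model$inputs))
      act[, r] <- act[, r] * grades[[j]][, model$rules[r, j]]
  act
}

#' FNN forward pass
#'
#' Standardizes the raw inputs with the model's stored constants, computes
#' all membership grades and rule activations, and returns the output
#' `y* = sum_r Wf_r * Pi_r`.
#'
#' @param model An `fnn_model`.
#' @param data Data frame containing the model's input columns (raw units).
#' @return Numeric vector `y*`, one value per row.
#' @export
fnn_forward <- function(model, data) {
  Z <- standardize_inputs(model, data)
  act <- rule_activations(model, grade_matrices(model, Z))
  as.numeric(act %*% model$Wf)
}

#' Classify an FNN output value
#'
#' @param y Numeric vector of FNN outputs `y*`.
#' @return Character vector: `"case"` for `y* > 0`, `"control"` for
#'   `y* < 0`, `"tie"` for exactly 0 (a tie is never a correct estimate).
#' @export
predict_class <- function(y) {
  if (!all(is.finite(y))) stop("non-finite y*")
  ifelse(y > 0, "case", ifelse(y < 0, "control", "tie"))
}

# number of correct estimations under the +1 case / -1 control coding
n_correct <- function(y, target) {
  sum((y > 0 & target > 0) | (y < 0 & target < 0))
}

#' Training configuration for the FNN
#'
#' @param learning_rate Gradient-descent step size (> 0). Default 0.05.
#' @param epochs Number of full-batch epochs (>= 0). Default 500.
#' @param seed Seed consumed for the data shuffle. Default 1.
#' @param tol Early-stopping tolerance on the epoch-to-epoch decrease of
#'   the mean squared error; 0 disables early stopping.
#' @param log_inputs Optional character vector of inputs to log-transform
#'   before standardization.
#' @return A list of class `fnn_config`.
#' @export
fnn_config <- function(learning_rate = 0.05, epochs = 500L, seed = 1L,
                       tol = 0, log_inputs = character(0)) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), tol = tol,
                 log_inputs = log_inputs), class = "fnn_config")
}

#' Train an FNN by gradient descent
#'
#' Full-batch gradient descent on the squared error
#' `sum_i (y*_i - t_i)^2` with targets `t = +1` (case) / `-1` (control),
#' updating the rule weights `Wf` and the membership centers `Wc` and
#' gradients `Wg` each epoch. Sign constraints (`Wg_high > 0`,
#' `Wg_low < 0`) are maintained by projection. Standardization constants
#' are the training data's mean and sd per input.
#'
#' @param data Complete-case data frame with the input columns and a
#'   `target` column coded +1 / -1 (see [analysis_table()]).
#' @param inputs Character vector of input columns (k of them).
#' @param config An [fnn_config()].
#' @return A trained `fnn_model`; `$loss` holds the per-epoch mean squared
#'   error.
#' @export
#' @examples
#' d <- data.frame(x = c(rnorm(50, -2), rnorm(50, 2)),
#'                 target = rep(c(-1, 1), each = 50))
#' m <- fnn_train(d, "x", fnn_config(epochs = 200))
#' mean(predict_class(fnn_forward(m, d)) == ifelse(d$target > 0, "case", "control"))
fnn_train <- function(data, inputs, config = fnn_config()) {
  if (!all(inputs %in% names(data))) stop("missing input columns")
  if (!"target" %in% names(data)) stop("data must carry a target column")
  t_ <- data$target
  if (!all(t_ %in% c(-1, 1))) stop("targets must be coded +1 / -1")
  if (sum(t_ == 1) < 2 || sum(t_ == -1) < 2)
    stop("need at least 2 subjects per class")

  for (li in intersect(config$log_inputs, inputs)) {
    if (any(data[[li]] <= 0)) stop("log transform requires positive values: ", li)
    data[[li]] <- log(data[[li]])
  }
  X <- as.matrix(data[, inputs, drop = FALSE])
  if (anyNA(X)) stop("training data must be complete-case for the inputs")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance input: ",
                          paste(inputs[scl == 0], collapse = ", "))

  model <- fnn_model(inputs, ctr, scl)
  model$log_inputs <- intersect(config$log_inputs, inputs)
  set.seed(config$seed)
  ord <- sample.int(nrow(X))           # shuffled presentation order
  Z <- sweep(sweep(X[ord, , drop = FALSE], 2, ctr), 2, scl, "/")
  t_ <- t_[ord]
  n <- nrow(Z); k <- length(inputs); R <- nrow(model$rules)
  lr <- config$learning_rate
  eps_g <- 1e-3
  losses <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    grades <- grade_matrices(model, Z)
    act <- rule_activations(model, grades)
    y <- as.numeric(act %*% model$Wf)
    e <- y - t_
    losses[ep] <- mean(e^2)

    # rule-weight gradient
    gWf <- as.numeric(crossprod(act, 2 * e)) / n

    gWc <- matrix(0, 2, k); gWg <- matrix(0, 2, k)
    for (j in seq_len(k)) {
      f <- grades[[j]]
      for (s in 1:2) {
        # dy/df_{j,s}: sum over rules using level s of input j of
        # Wf_r times the partial product excluding input j
        dyd <- numeric(n)
        for (r in seq_len(R)) {
          if (model$rules[r, j] != s) next
          pp <- rep(1, n)
          for (m in seq_len(k)) if (m != j)
            pp <- pp * grades[[m]][, model$rules[r, m]]
          dyd <- dyd + model$Wf[r] * pp
        }
        fp <- f[, s] * (1 - f[, s])
        common <- 2 * e * dyd * fp
        gWg[s, j] <- sum(common * Z[, j]) / n
        gWc[s, j] <- sum(-common) / n
      }
    }

    model$Wf <- model$Wf - lr * gWf
    model$Wc <- model$Wc - lr * gWc
    model$Wg <- model$Wg - lr * gWg
    # projection keeps f_high non-decreasing and f_low non-increasing
    model$Wg["high", ] <- pmax(model$Wg["high", ], eps_g)
    model$Wg["low", ] <- pmin(model$Wg["low", ], -eps_g)

    if (config$tol > 0 && ep > 1 &&
        losses[ep - 1] - losses[ep] < config$tol) {
      losses <- losses[seq_len(ep)]
      break
    }
  }
  model$loss <- losses
  model
}

# forward pass honoring a trained model's log-input transform
fnn_predict <- function(model, data) {
  for (li in model$log_inputs %||% character(0)) data[[li]] <- log(data[[li]])
  fnn_forward(model, data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore an FNN model as JSON
#'
#' @param model An `fnn_model`.
#' @param path File path.
#' @return `fnn_to_json` invisibly returns `path`; `fnn_from_json` returns
#'   the restored `fnn_model`.
#' @export
fnn_to_json <- function(model, path) {
  obj <- list(inputs = model$inputs, center = as.list(model$center),
              scale = as.list(model$scale),
              Wc = list(low = unname(model$Wc["low", ]),
                        high = unname(model$Wc["high", ])),
              Wg = list(low = unname(model$Wg["low", ]),
                        high = unname(model$Wg["high", ])),
              Wf = as.list(model$Wf),
              log_inputs = model$log_inputs %||% character(0))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fnn_to_json
#' @export
fnn_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- fnn_model(obj$inputs, unlist(obj$center), unlist(obj$scale))
  m$Wc["low", ] <- obj$Wc$low;  m$Wc["high", ] <- obj$Wc$high
  m$Wg["low", ] <- obj$Wg$low;  m$Wg["high", ] <- obj$Wg$high
  m$Wf[] <- unlist(obj$Wf)
  m$log_inputs <- as.character(obj$log_inputs)
  m
}
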