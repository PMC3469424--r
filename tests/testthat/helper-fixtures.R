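# Shared fixtures: small deterministic datasets built in code.

# 1-D linearly separable toy set: cases at x > 1, controls at x < -1
toy_separable_1d <- function(n = 200, seed = 42) {
  set.seed(seed)
  data.frame(x = c(runif(n / 2, 1, 3), runif(n / 2, -3, -1)),
             target = rep(c(1, -1), each = n / 2))
}

# 2-D interaction toy set: case probability high only when BOTH inputs
# are high (no XOR structure; the high/high cell carries the signal)
toy_interaction_2d <- function(n = 400, seed = 7) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  p <- plogis(-2 + 2.5 * (x1 > 0.3) * (x2 > 0.3))
  data.frame(x1 = x1, x2 = x2, target = ifelse(rbinom(n, 1, p) == 1, 1, -1))
}

# a tiny but labelable synthetic cohort
small_cohort <- function(n = 300, seed = 3, ...) {
  generate_cohort(cohort_spec("original", n_subjects = n, seed = seed, ...))
}

# independent re-implementation of the weighted accuracy formula
oracle_weighted_accuracy <- function(ct, nt, cv, nv) {
  (ct / nt) * (100 / 3) + (cv / nv) * (200 / 3)
}

# independent 4-term forward pass for a k = 2 model
oracle_forward_k2 <- function(model, data) {
  z1 <- (data[[model$inputs[1]]] - model$center[1]) / model$scale[1]
  z2 <- (data[[model$inputs[2]]] - model$center[2]) / model$scale[2]
  f <- function(z, s, j) plogis(model$Wg[s, j] * z - model$Wc[s, j])
  model$Wf["low.low"]   * f(z1, "low", 1)  * f(z2, "low", 2) +
  model$Wf["high.low"]  * f(z1, "high", 1) * f(z2, "low", 2) +
  model$Wf["low.high"]  * f(z1, "low", 1)  * f(z2, "high", 2) +
  model$Wf["high.high"] * f(z1, "high", 1) * f(z2, "high", 2)
}
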