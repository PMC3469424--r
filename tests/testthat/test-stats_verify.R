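test_that("unadjusted logistic OR equals the 2x2 cross-product ratio", {
  make_2x2 <- function(a, b, c_, d_) {
    data.frame(x = rep(c(1, 0, 1, 0), c(a, b, c_, d_)),
               target = rep(c(1, 1, -1, -1), c(a, b, c_, d_)))
  }
  # 30 exposed cases, 20 unexposed cases, 10 exposed controls, 40 unexposed
  r <- logistic_or(make_2x2(30, 20, 10, 40), "x", model_id = 1)
  expect_equal(r$or, 6.0, tolerance = 1e-6)
  expect_true(r$ci_low < r$or && r$or < r$ci_high)

  set.seed(15)
  for (i in 1:200) {
    t4 <- sample(5:60, 4, replace = TRUE)
    r <- logistic_or(make_2x2(t4[1], t4[2], t4[3], t4[4]), "x", model_id = 1)
    oracle <- (t4[1] * t4[4]) / (t4[2] * t4[3])
    expect_equal(r$or, oracle, tolerance = 1e-6)
  }
})

test_that("the doubling transform gives a scale-invariant per-doubling OR", {
  set.seed(16)
  d <- data.frame(x = rlnorm(400, 3, 0.5),
                  target = rep(c(1, -1), 200))
  d$target <- ifelse(runif(400) < plogis(0.8 * scale(log(d$x))), 1, -1)
  r1 <- logistic_or(d, "x", transform = "doubling", model_id = 1)
  d2 <- d; d2$x <- d$x * 1000
  r2 <- logistic_or(d2, "x", transform = "doubling", model_id = 1)
  expect_equal(r1$or, r2$or, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
  d$x[1] <- 0
  expect_error(logistic_or(d, "x", transform = "doubling"), "positive")
})

test_that("adjusted models use the nested adjustment ladder", {
  ch <- small_cohort(n = 1500, seed = 17)
  ana <- analysis_table(ch)
  r1 <- logistic_or(ana, "ggt", "doubling", model_id = 1)
  r3 <- logistic_or(ana, "ggt", "doubling", model_id = 3)
  expect_gt(r1$or, 1)        # gamma-GTP drives onset in the generator
  expect_lt(r1$p, 0.05)
  expect_lte(r3$n, r1$n)     # larger adjustment set, more complete-case loss
  # a predictor with no onset effect has OR near 1 at large n
  ch0 <- generate_cohort(cohort_spec("original", n_subjects = 5000, seed = 18,
                                     onset = list(b_ggt = 0, b_wbc = 0,
                                                  b_interaction = 0,
                                                  b0 = -1.2)))
  r0 <- logistic_or(analysis_table(ch0), "bun", model_id = 1)
  expect_gt(r0$or, 0.9); expect_lt(r0$or, 1.1)
})

test_that("signed eta equals the point-biserial correlation", {
  r <- correlation_eta(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$eta, 0.8944272, tolerance = 1e-6)

  set.seed(19)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    v <- rnorm(n); g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) next
    r <- correlation_eta(v, g)
    expect_equal(r$eta, cor(v, g), tolerance = 1e-10)
    # magnitude equals the classical correlation-ratio formula
    gm <- mean(v)
    ss_between <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
    ss_total <- sum((v - gm)^2)
    expect_equal(abs(r$eta), sqrt(ss_between / ss_total), tolerance = 1e-10)
    # p equals the two-sample pooled t test on the group means
    expect_equal(r$p, t.test(v ~ g, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(correlation_eta(c(1, 2, 1, 2), c(0, 0, 1, 1))$eta, 0)
  expect_error(correlation_eta(rep(1, 10), rep(c(0, 1), 5)), "constant")
})

test_that("default-cohort habit correlations sit in the expected bands", {
  ch <- generate_cohort(cohort_spec("original", n_subjects = 2000, seed = 20))
  et <- eta_table(ch)
  wbc_smk <- et$eta[et$characteristic == "wbc" & et$habit == "smoking"]
  ggt_smk <- et$eta[et$characteristic == "ggt" & et$habit == "smoking"]
  ggt_alc <- et$eta[et$characteristic == "ggt" & et$habit == "alcohol"]
  expect_gt(wbc_smk, 0.25); expect_lt(wbc_smk, 0.50)
  expect_gt(ggt_smk, -0.1); expect_lt(ggt_smk, 0.2)
  expect_gt(ggt_alc, 0.05)
})

test_that("group comparisons reproduce printed contingency p-values", {
  # smoking habit 2x2: 51/75 cases vs 81/151 healthy controls
  p_smk <- group_compare(c(51, 75), c(81, 151), type = "categorical")$p
  expect_lt(abs(p_smk - 3.94e-2) / 3.94e-2, 0.05)
  # alcohol habit 2x2: 1693/2194 vs 1704/2195
  p_alc <- group_compare(c(1693, 2194), c(1704, 2195), type = "categorical")$p
  expect_lt(abs(p_alc - 0.712) / 0.712, 0.02)
  # identical groups -> chi-square 0, p = 1
  expect_equal(group_compare(c(30, 60), c(30, 60), type = "categorical")$p, 1)

  # chi-square (no correction) p equals the squared two-proportion z test
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    s1 <- sample(1:(n1 - 1), 1); s2 <- sample(1:(n2 - 1), 1)
    p_chi <- group_compare(c(s1, n1), c(s2, n2), type = "categorical")$p
    ph <- (s1 + s2) / (n1 + n2)
    z <- (s1 / n1 - s2 / n2) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
    expect_equal(p_chi, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }

  # continuous: pooled-variance Student by default
  set.seed(22)
  x <- rnorm(40, 1); y <- rnorm(50)
  expect_equal(group_compare(x, y)$p,
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(group_compare(x, y, welch = TRUE)$p,
               t.test(x, y)$p.value)
})

test_that("characteristics tables summarize both strata with p-values", {
  ch <- small_cohort(n = 800, seed = 23)
  tab <- characteristics_table(ch)
  expect_true(all(c("bmi", "sbp", "alcohol", "smoking") %in%
                    tab$characteristic))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  n_case <- sum(ch$baseline$label == "case")
  n_hc <- sum(ch$baseline$label == "healthy_control")
  expect_true(all(tab$n_case <= n_case) && all(tab$n_control <= n_hc))
  # healthy controls are leaner at baseline than developing cases (the
  # supercontrol selection truncates the component distributions)
  b <- ch$baseline
  expect_gt(mean(b$bmi[b$label == "case"]),
            mean(b$bmi[b$label == "healthy_control"]))
  expect_lt(tab$p[tab$characteristic == "sbp"], 0.05)
  expect_equal(nrow(characteristics_table(ch$baseline[0, ])), 0)
})
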