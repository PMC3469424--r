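test_that("baseline generation honors the spec marginals and determinism", {
  spec <- cohort_spec("original", n_subjects = 0, seed = 1)
  expect_equal(nrow(generate_baseline(spec)), 0)

  spec <- cohort_spec("original", n_subjects = 3000, seed = 5)
  b <- generate_baseline(spec)
  expect_equal(nrow(b), 3000)
  expect_identical(b, generate_baseline(spec))           # fixed seed
  expect_false(identical(b, generate_baseline(cohort_spec("original",
                                                          n_subjects = 3000,
                                                          seed = 6))))
  # means within 3 standard errors of the spec targets
  for (ch in c("sbp", "dbp", "hdl", "glucose", "bun", "hemoglobin")) {
    par <- spec[[ch]]
    expect_lt(abs(mean(b[[ch]]) - par$mean), 3 * par$sd / sqrt(3000) + 0.05)
  }
  expect_true(all(b$ggt > 0) && all(b$tg > 0))
  # BMI consistent with height/weight
  expect_equal(b$weight / (b$height / 100)^2, b$bmi, tolerance = 1e-12)
  # habit indicators near spec prevalence
  expect_lt(abs(mean(b$alcohol) - spec$prevalence$alcohol), 0.03)
  expect_lt(abs(mean(b$smoking) - spec$prevalence$smoking), 0.03)
})

test_that("association strengths propagate (and vanish when zeroed)", {
  spec0 <- cohort_spec("original", n_subjects = 5000, seed = 9,
                       ggt = list(alcohol_shift = 0, age_slope = 0),
                       wbc = list(smoking_shift = 0))
  b0 <- generate_baseline(spec0)
  expect_lt(abs(cor(b0$wbc, b0$smoking)), 0.05)
  expect_lt(abs(cor(log(b0$ggt), b0$alcohol)), 0.05)

  spec <- cohort_spec("original", n_subjects = 5000, seed = 9)
  b <- generate_baseline(spec)
  expect_gt(mean(log(b$ggt[b$alcohol == 1])), mean(log(b$ggt[b$alcohol == 0])))
  expect_gt(mean(b$wbc[b$smoking == 1]), mean(b$wbc[b$smoking == 0]))
  expect_gt(cor(log(b$ggt), b$age), 0.1)
})

test_that("healthy-stratum gamma-GTP means match the two study presets", {
  b1 <- generate_cohort(cohort_spec("original", n_subjects = 5000,
                                    seed = 11))$baseline
  m1 <- mean(b1$ggt[b1$label == "healthy_control"], na.rm = TRUE)
  expect_lt(abs(m1 - 16.3) / 16.3, 0.15)

  b2 <- generate_cohort(cohort_spec("replication", n_subjects = 5000,
                                    seed = 12))$baseline
  m2 <- mean(b2$ggt[b2$label == "healthy_control"], na.rm = TRUE)
  expect_lt(abs(m2 - 27.3) / 27.3, 0.15)
})

test_that("follow-up onset follows the logistic model in the spec", {
  # degenerate incidence: hugely negative intercept, zero effects
  spec <- cohort_spec("original", n_subjects = 400, seed = 2,
                      onset = list(b0 = -30, b_ggt = 0, b_wbc = 0,
                                   b_interaction = 0),
                      bmi = list(mean = 20, sd = 1.2, floor = 15),
                      sbp = list(mean = 112, sd = 7, floor = 70),
                      dbp = list(mean = 70, sd = 6, floor = 40),
                      tg = list(meanlog = log(70), sdlog = 0.3),
                      glucose = list(mean = 88, sd = 5, floor = 50),
                      followup = list(drift = c(bmi = 0, sbp = 0, dbp = 0,
                                                tg_log = 0, hdl = 0,
                                                glucose = 0)))
  ch <- label_cohort(simulate_followup(generate_baseline(spec), spec))
  expect_equal(sum(ch$baseline$label == "case"), 0)

  # pure interaction: per-quadrant incidence matches the mean of the
  # closed-form per-subject logistic probabilities (binomial error)
  spec <- cohort_spec("original", n_subjects = 5000, seed = 21,
                      onset = list(b0 = -2.5, b_ggt = 0, b_wbc = 0,
                                   b_interaction = 1),
                      bmi = list(mean = 20, sd = 1.2, floor = 15),
                      sbp = list(mean = 112, sd = 7, floor = 70),
                      dbp = list(mean = 70, sd = 6, floor = 40),
                      tg = list(meanlog = log(70), sdlog = 0.3),
                      glucose = list(mean = 88, sd = 5, floor = 50),
                      followup = list(drift = c(bmi = 0, sbp = 0, dbp = 0,
                                                tg_log = 0, hdl = 0,
                                                glucose = 0)))
  b <- generate_baseline(spec)
  p <- onset_probability(b, spec)
  ch <- label_cohort(simulate_followup(b, spec))
  lab <- ch$baseline$label
  hi1 <- log(b$ggt) > median(log(b$ggt)); hi2 <- b$wbc > median(b$wbc)
  for (q in list(hi1 & hi2, !hi1 & !hi2)) {
    obs <- mean(lab[q] == "case")
    exp_p <- mean(p[q]) * mean(lab[q] != "excluded")
    expect_lt(abs(obs - exp_p), 3 * sqrt(exp_p * (1 - exp_p) / sum(q)) + 0.01)
  }
  inc_hh <- mean(lab[hi1 & hi2] == "case")
  inc_ll <- mean(lab[!hi1 & !hi2] == "case")
  expect_gt(inc_hh, inc_ll)
})

test_that("default preset yields a roughly 1:2 case:healthy-control ratio", {
  counts <- sapply(1:3, function(s) {
    lab <- generate_cohort(cohort_spec("original", seed = s))$baseline$label
    c(case = sum(lab == "case"), hc = sum(lab == "healthy_control"))
  })
  ratio <- sum(counts["case", ]) / sum(counts["hc", ])
  expect_gt(ratio, 77 / 152 / 1.6)
  expect_lt(ratio, 77 / 152 * 1.6)
})

test_that("gamma-GTP and WBC correlate non-negatively in the healthy stratum", {
  # both share lifestyle drivers (drinking/smoking co-occur freely), so
  # their healthy-stratum association must not be negative
  b <- generate_cohort(cohort_spec("original", n_subjects = 5000, seed = 33,
                                   missingness = c(ggt = 0, wbc = 0)))$baseline
  hc <- b[b$label == "healthy_control", ]
  expect_gte(cor(log(hc$ggt), hc$wbc), -0.03)
})

test_that("missingness is MCAR at the requested rate", {
  spec <- cohort_spec("original", n_subjects = 5000, seed = 4)
  b <- generate_baseline(spec)
  expect_identical(inject_missingness(b, spec, rates = c(ggt = 0)), b)

  bm <- inject_missingness(b, spec, rates = c(ggt = 0.2, wbc = 0.2))
  expect_lt(abs(mean(is.na(bm$ggt)) - 0.2), 0.02)
  expect_lt(abs(mean(is.na(bm$wbc)) - 0.2), 0.02)
  # independence: complete cases for the pair ~ 0.64 n
  cc <- mean(complete.cases(bm[, c("ggt", "wbc")]))
  expect_lt(abs(cc - 0.64), 0.03)
  expect_error(inject_missingness(b, spec, rates = c(ggt = 1)), "missingness")
})

test_that("zero onset effects leave case and control gamma-GTP alike", {
  # two-sample KS on case vs healthy-control gamma-GTP across seeds
  fails <- 0L
  for (s in 1:8) {
    spec <- cohort_spec("original", n_subjects = 2000, seed = 100 + s,
                        onset = list(b_ggt = 0, b_wbc = 0, b_interaction = 0,
                                     b0 = -2.2),
                        missingness = c(ggt = 0))
    b <- generate_cohort(spec)$baseline
    ks <- suppressWarnings(ks.test(b$ggt[b$label == "case"],
                                   b$ggt[b$label == "healthy_control"]))
    if (ks$p.value <= 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})
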