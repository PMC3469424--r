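# reference JASSO rule, written independently of the implementation
oracle_mets <- function(ob, bp, dl, gl) ob && (bp + dl + gl) >= 2

test_that("component flags follow the JASSO thresholds, boundaries inclusive", {
  f <- component_flags(list(bmi = 26, sbp = 135, dbp = 80, tg = 160,
                            hdl = 50, glucose = 100))
  expect_true(f$obesity); expect_true(f$raised_bp)
  expect_true(f$dyslipidemia); expect_false(f$raised_glucose)
  expect_equal(f$n_components, 3)

  f <- component_flags(list(bmi = 20, sbp = 110, dbp = 70, tg = 80,
                            hdl = 60, glucose = 90))
  expect_equal(f$n_components, 0)

  # exact boundary panel: all four flags true
  f <- component_flags(list(bmi = 25.0, sbp = 100, dbp = 85, tg = 150,
                            hdl = 45, glucose = 110))
  expect_true(f$obesity && f$raised_bp && f$dyslipidemia && f$raised_glucose)

  # waist takes precedence over BMI; HDL < 40 alone flags dyslipidemia
  f <- component_flags(list(waist = 85, bmi = 20, sbp = 100, dbp = 70,
                            tg = 100, hdl = 39.9, glucose = 90))
  expect_true(f$obesity); expect_true(f$dyslipidemia)

  # partially observed "and/or" pairs are indeterminate unless TRUE
  f <- component_flags(list(bmi = 20, sbp = 120, tg = 100, hdl = 50,
                            glucose = 90))
  expect_true(is.na(f$raised_bp)); expect_true(is.na(f$n_components))
  f <- component_flags(list(bmi = 20, sbp = 135, tg = 100, hdl = 50,
                            glucose = 90))
  expect_true(f$raised_bp)
  expect_error(component_flags(list(bmi = NA)), "determinable")
})

test_that("is_mets agrees with the truth table over all 16 combinations", {
  for (ob in c(FALSE, TRUE)) for (bp in c(FALSE, TRUE))
    for (dl in c(FALSE, TRUE)) for (gl in c(FALSE, TRUE)) {
      flags <- list(obesity = ob, raised_bp = bp, dyslipidemia = dl,
                    raised_glucose = gl)
      expect_identical(is_mets(flags), oracle_mets(ob, bp, dl, gl),
                       info = paste(ob, bp, dl, gl))
    }
  # obesity is mandatory
  expect_false(is_mets(list(obesity = FALSE, raised_bp = TRUE,
                            dyslipidemia = TRUE, raised_glucose = TRUE)))
})

test_that("cohort labeling follows the case/supercontrol/exclusion rules", {
  clean <- data.frame(bmi = 20, sbp = 110, dbp = 70, tg = 80, hdl = 60,
                      glucose = 90)
  mets <- data.frame(bmi = 27, sbp = 140, dbp = 90, tg = 200, hdl = 35,
                     glucose = 120)
  mild <- data.frame(bmi = 20, sbp = 135, dbp = 70, tg = 80, hdl = 60,
                     glucose = 90)
  yrs <- function(...) do.call(rbind, list(...))

  # MetS at year 5 -> case
  expect_equal(assign_cohort_label(clean, yrs(clean, clean, clean, clean,
                                              mets), FALSE), "case")
  # zero components every year -> healthy control
  expect_equal(assign_cohort_label(clean, yrs(clean, clean, clean), FALSE),
               "healthy_control")
  # a single raised-BP year demotes to normal control
  expect_equal(assign_cohort_label(clean, yrs(clean, mild, clean), FALSE),
               "normal_control")
  # medication overrides everything
  expect_equal(assign_cohort_label(clean, yrs(mets), TRUE), "excluded")
  # baseline MetS cannot "develop" MetS -> excluded
  expect_equal(assign_cohort_label(mets, yrs(mets), FALSE), "excluded")
  # partially observed panel blocks healthy_control
  incomplete <- data.frame(bmi = 20, sbp = 110, dbp = 70, tg = NA, hdl = 60,
                           glucose = 90)
  expect_equal(assign_cohort_label(clean, yrs(clean, incomplete), FALSE),
               "normal_control")
  expect_error(assign_cohort_label(clean, clean[0, ], FALSE), "panel")
})

test_that("labels partition a cohort and supercontrols are never MetS", {
  ch <- small_cohort(n = 400, seed = 8)
  lab <- ch$baseline$label
  expect_true(all(lab %in% c("case", "healthy_control", "normal_control",
                             "excluded")))
  expect_equal(length(lab), 400)
  # healthy controls: zero components in every follow-up panel
  hc_ids <- ch$baseline$subject_id[lab == "healthy_control"]
  fu <- ch$followup[ch$followup$subject_id %in% hc_ids, ]
  ncomp <- vapply(seq_len(nrow(fu)),
                  function(i) component_flags(fu[i, ])$n_components,
                  integer(1))
  expect_true(all(ncomp == 0))
  # medicated subjects are always excluded
  med <- with(ch$baseline, med_antihypertensive + med_lipid_lowering +
                med_antidiabetic > 0)
  expect_true(all(lab[med] == "excluded"))
})

test_that("analysis_table keeps the two strata with +1/-1 coding", {
  ch <- small_cohort(n = 400, seed = 8)
  ana <- analysis_table(ch)
  expect_setequal(unique(ana$label), c("case", "healthy_control"))
  expect_identical(sort(unique(ana$target)), c(-1, 1))
  expect_equal(sum(ana$target == 1), sum(ch$baseline$label == "case"))
})
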