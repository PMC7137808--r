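test_that("hypertension rule: self-report OR strict BP thresholds", {
  coh <- build_cohort(7,
                      sbp2 = c(144, 140, 120, NA, 142, 120, NA),
                      sbp3 = c(142, 140, 120, NA, 140, 120, NA),
                      dbp2 = c(80, 90, 80, NA, NA, 92, NA),
                      dbp3 = c(80, 90, 80, NA, NA, 90, NA),
                      dx_hypertension = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                                          FALSE, FALSE))
  cl <- classify_hypertension(coh)
  # 143 mmHg systolic alone; exact 140/90 are negative (strict >)
  expect_equal(cl$hypertension,
               c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, NA))
  expect_equal(cl$hypertension_source[c(1, 4)], c("measured", "self_report"))
  # sbp 141 with missing dbp is sufficient; sbp normal with missing dbp
  # cannot rule out a diastolic elevation
  coh2 <- build_cohort(2, sbp2 = c(142, 120), sbp3 = c(140, 120),
                       dbp2 = NA, dbp3 = NA)
  expect_equal(classify_hypertension(coh2)$hypertension, c(TRUE, NA))
})

test_that("diabetes rule: any strict criterion, missing only when no info", {
  coh <- build_cohort(6,
                      hba1c = c(6.6, 6.5, NA, NA, NA, NA),
                      fasting_glucose = c(NA, NA, 126, NA, NA, NA),
                      random_glucose = c(NA, NA, NA, 201, NA, NA),
                      dx_diabetes = c(FALSE, FALSE, FALSE, FALSE, TRUE, NA))
  cl <- classify_diabetes(coh)
  expect_equal(cl$diabetes, c(TRUE, FALSE, FALSE, TRUE, TRUE, NA))
  expect_equal(cl$diabetes_source[c(1, 5)], c("measured", "self_report"))
})

test_that("ADL impairment uses moderate-or-worse, some-or-worse for walking", {
  coh <- build_cohort(5,
                      adl_dressing = c(1, 2, 3, 4, NA),
                      adl_walking = c(0, 2, 4, 0, 0))
  cl <- classify_adl(coh)
  expect_equal(cl$adl_dressing, c(FALSE, TRUE, TRUE, TRUE, NA))
  expect_equal(cl$adl_walking, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # any_adl is the missing-aware OR of the six items
  expect_equal(cl$any_adl, c(FALSE, TRUE, TRUE, TRUE, NA))
})

test_that("classifiers are monotone in each input and never true from nothing", {
  # worsening any ADL response never clears a flag
  for (item in c("adl_walking", "adl_dressing", "adl_eating")) {
    flags <- sapply(0:4, function(lv) {
      args <- list(n = 1); args[[item]] <- lv
      classify_adl(do.call(build_cohort, args))[[item]]
    })
    expect_true(all(diff(flags) >= 0))
  }
  # wholly missing inputs give missing, not positive
  blank <- build_cohort(1,
                        sbp1 = NA, sbp2 = NA, sbp3 = NA,
                        dbp1 = NA, dbp2 = NA, dbp3 = NA,
                        random_glucose = NA, fasting_glucose = NA,
                        hba1c = NA,
                        dx_hypertension = NA, dx_diabetes = NA,
                        adl_walking = NA, adl_transfers = NA,
                        adl_toileting = NA, adl_dressing = NA,
                        adl_bathing = NA, adl_eating = NA)
  expect_true(is.na(classify_hypertension(blank)$hypertension))
  expect_true(is.na(classify_diabetes(blank)$diabetes))
  expect_true(is.na(classify_adl(blank)$any_adl))
})

test_that("clinical_profile assembles classifiers and pass-through flags", {
  coh <- build_cohort(2, dx_tb = c(TRUE, FALSE), dx_heart = c(FALSE, TRUE))
  cp <- clinical_profile(coh)
  expect_equal(cp$tb, c(TRUE, FALSE))
  expect_equal(cp$heart, c(FALSE, TRUE))
  expect_true(all(c("hypertension", "diabetes", "any_adl") %in% names(cp)))
})
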