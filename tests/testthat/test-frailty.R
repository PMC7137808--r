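test_that("covariate adjustment reproduces the published worked examples", {
  adj <- reference_adjustments()
  expect_equal(adjust_measure(44.9, 21.6, adj$grip.male), 44.9)
  expect_equal(adjust_measure(50, 31.6, adj$grip.male), 38.3)
  expect_equal(adjust_measure(0.888, 162, adj$walk.female), 0.888)
  expect_true(is.na(adjust_measure(NA, 25, adj$grip.male)))
})

test_that("fitted adjustment slope matches the closed-form OLS oracle", {
  # exact linear relation: slope recovered exactly
  n <- 60
  bmi <- seq(18, 30, length.out = n)
  coh <- build_cohort(n, bmi = bmi, grip1 = 2 * bmi, grip2 = 2 * bmi,
                      grip3 = 2 * bmi, grip4 = 2 * bmi)
  m <- fit_adjustment(coh, "grip", "male")
  expect_equal(m$slope, 2, tolerance = 1e-10)
  expect_equal(m$reference, 24)

  # noisy stratum with known slope 1.17: equals the oracle on the same
  # draws, and is close to the generating slope
  set.seed(88)
  n <- 500
  bmi <- rnorm(n, 22, 3.5)
  grip <- 40 + 1.17 * (bmi - 22) + rnorm(n, 0, 5)
  coh <- build_cohort(n, bmi = bmi, grip1 = grip, grip2 = grip,
                      grip3 = grip, grip4 = grip)
  m <- fit_adjustment(coh, "grip", "male")
  expect_equal(m$slope, ols_slope_oracle(bmi, grip), tolerance = 1e-10)
  expect_lt(abs(m$slope - 1.17), 0.2)

  expect_error(fit_adjustment(build_cohort(20), "grip", "male"),
               "zero variance")
  expect_error(fit_adjustment(build_cohort(5, bmi = rnorm(5, 22)),
                              "grip", "male"), ">= 10")
})

test_that("derived cutoffs follow the type-7 quantile rule", {
  # identity adjustments isolate the quantile rule itself
  adj0 <- list(grip.male = adjustment_model("male", "grip", 0, 0),
               grip.female = adjustment_model("female", "grip", 0, 0),
               walk.male = adjustment_model("male", "walk", 0, 0),
               walk.female = adjustment_model("female", "walk", 0, 0))
  n <- 100
  grips <- 1:100
  sexes <- rep(c("male", "female"), each = 50)
  coh <- build_cohort(n, sex = sexes,
                      grip1 = grips, grip2 = grips, grip3 = grips,
                      grip4 = grips)
  cuts <- derive_cutoffs(coh, adjustments = adj0)
  expect_equal(unname(cuts$grip["male"]), quantile7_oracle(grips[1:50], 0.2))
  expect_equal(unname(cuts$grip["female"]),
               quantile7_oracle(grips[51:100], 0.2))
  expect_lt(abs(cuts$grip["male"] - quantile(grips[1:50], 0.2)), 1e-12)
  expect_equal(unname(cuts$sitting["male"]), quantile7_oracle(rep(20, 50), 0.8))

  # large near-normal stratum: cutoff close to the inverse-CDF value
  set.seed(5)
  z <- rnorm(20000)
  coh2 <- build_cohort(20000, sex = rep(c("male", "female"), each = 10000),
                       grip1 = 40 + z, grip2 = 40 + z,
                       grip3 = 40 + z, grip4 = 40 + z)
  cuts2 <- derive_cutoffs(coh2, adjustments = adj0)
  expect_lt(abs(cuts2$grip["male"] - (40 + qnorm(0.2))), 0.05)

  expect_error(derive_cutoffs(build_cohort(4, bmi = c(20, 21, 22, 23))),
               "10")
})

test_that("identical values collapse the cutoff onto that value", {
  set.seed(61)
  coh <- build_cohort(40, sex = rep(c("male", "female"), 20),
                      bmi = rnorm(40, 22, 2), height = rnorm(40, 167, 6))
  cuts <- derive_cutoffs(coh)
  # all sitting hours tie at 20: the cutoff is that value, and the
  # non-strict >= rule flags every participant
  expect_equal(unname(cuts$sitting["male"]), 20)
  fl <- component_flags(coh, cuts)
  expect_true(all(fl$low_activity))
  # all grips tie at 40 with a ~zero fitted slope: strict < flags no one
  expect_false(any(fl$low_grip))
})

test_that("component flags respect the printed strictness at each boundary", {
  cuts <- reference_cutoffs()
  # adjusted grip exactly at the cutoff is NOT low (strict <)
  coh <- build_cohort(4,
                      bmi = 21.6,
                      grip1 = c(37.1, 37.0, 37.1, 37.0), grip2 = 30,
                      grip3 = 30, grip4 = 30,
                      sitting_hours = c(34, 33.9, 36, 20),
                      weight_change = c(4, 5, -4, 0),
                      exh_effort = c(2, 1, 0, 0),
                      exh_get_going = c(0, 1, 3, 0),
                      sex = c("male", "male", "female", "female"),
                      height = c(172, 172, 162, 162),
                      walk1 = c(4 / 0.821, 4 / 0.820, 4 / 0.720, 4),
                      walk2 = NA)
  fl <- component_flags(coh, cuts)
  # rows 3-4 are women far above the 25.0 kg female cutoff
  expect_equal(fl$low_grip, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fl$low_walk, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fl$low_activity, c(TRUE, FALSE, TRUE, FALSE))  # >= rule
  expect_equal(fl$weight_loss, c(FALSE, TRUE, FALSE, FALSE))  # strict > 4
  expect_equal(fl$exhaustion, c(TRUE, FALSE, TRUE, FALSE))    # either item
})

test_that("missing inputs propagate to missing flags, never to positives", {
  cuts <- reference_cutoffs()
  coh <- build_cohort(2,
                      grip1 = NA, grip2 = NA, grip3 = NA, grip4 = NA,
                      sitting_hours = NA, weight_change = NA,
                      exh_effort = c(NA, 3), exh_get_going = c(0, NA))
  fl <- component_flags(coh, cuts)
  expect_true(all(is.na(fl$low_grip)))
  expect_true(all(is.na(fl$low_activity)))
  expect_true(all(is.na(fl$weight_loss)))
  expect_true(all(is.na(fl$exhaustion)))
})

test_that("scoring maps points to categories exactly", {
  fl <- data.frame(weight_loss = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                   exhaustion = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                   low_grip = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                   low_walk = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                   low_activity = c(FALSE, FALSE, NA, FALSE, TRUE))
  sc <- score_frailty(fl)
  expect_equal(sc$score, c(3L, 0L, NA, 2L, 5L))
  expect_equal(as.character(sc$category),
               c("frail", "non_frail", "unable_to_score", "prefrail", "frail"))
  # documented alternative: >= 3 observed positives labels frail anyway
  alt <- score_frailty(fl, strict_missing = FALSE)
  expect_equal(as.character(alt$category)[3], "frail")
})

test_that("scoring is monotone: adding a positive never moves toward non-frail", {
  lev <- c("non_frail", "prefrail", "frail")
  set.seed(3)
  for (rep in 1:50) {
    flags <- as.logical(rbinom(5, 1, 0.4))
    base <- data.frame(t(flags))
    names(base) <- c("weight_loss", "exhaustion", "low_grip", "low_walk",
                     "low_activity")
    c0 <- match(as.character(score_frailty(base)$category), lev)
    for (j in which(!flags)) {
      up <- base; up[[j]] <- TRUE
      c1 <- match(as.character(score_frailty(up)$category), lev)
      expect_gte(c1, c0)
    }
  }
})

test_that("derive-mode flags about 20% per sex and partition the cohort", {
  coh <- generate_cohort(complete_config(3000, 17))
  fit <- frailty_fit(coh)
  for (s in c("male", "female")) {
    i <- coh$sex == s
    for (cm in c("low_grip", "low_walk"))
      expect_lt(abs(mean(fit$scores[[cm]][i]) - 0.20), 0.01)
  }
  expect_equal(sum(table(fit$scores$category)), nrow(coh))
  expect_equal(sum(is.na(fit$scores$score)),
               sum(fit$scores$category == "unable_to_score"))
})

test_that("fixed mode reproduces derive mode on the deriving cohort", {
  coh <- generate_cohort(cohort_config(n = 600, seed = 29))
  derived <- frailty_fit(coh)
  fixed <- frailty_fit(coh, cutoffs = derived$cutoffs,
                       adjustments = derived$adjustments)
  expect_identical(fixed$scores, derived$scores)
})

test_that("fixed mode with the published cutoffs flags the worked example", {
  coh <- build_cohort(1, bmi = 21.6, grip1 = 37.0, grip2 = 30, grip3 = 30,
                      grip4 = 30)
  fit <- frailty_fit(coh, cutoffs = reference_cutoffs())
  expect_true(fit$scores$low_grip)
})

test_that("a fitted model predicts new cohorts with the stored cutoffs", {
  train <- generate_cohort(cohort_config(n = 500, seed = 41))
  test <- generate_cohort(cohort_config(n = 200, seed = 42))
  fit <- frailty_fit(train)
  pred <- predict(fit, test)
  expect_equal(nrow(pred), 200)
  direct <- frailty_fit(test, cutoffs = fit$cutoffs,
                        adjustments = fit$adjustments)
  expect_identical(pred, direct$scores)
  expect_named(coef(fit), c("grip_male", "grip_female", "walk_male",
                            "walk_female", "sitting_male", "sitting_female",
                            "weight_loss_kg", "exhaustion_level"))
})

test_that("cutoff sets survive a JSON round trip", {
  coh <- generate_cohort(cohort_config(n = 400, seed = 55))
  cuts <- derive_cutoffs(coh)
  path <- withr::local_tempfile(fileext = ".json")
  write_cutoffs(cuts, path)
  back <- read_cutoffs(path)
  expect_equal(unclass(back), unclass(cuts), tolerance = 1e-12)
  fixed1 <- frailty_fit(coh, cutoffs = cuts)
  fixed2 <- frailty_fit(coh, cutoffs = back)
  expect_equal(fixed1$scores, fixed2$scores)
})
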