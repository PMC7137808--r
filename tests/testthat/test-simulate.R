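test_that("generation is deterministic under a fixed config and seed", {
  cfg <- cohort_config(n = 40, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- generate_cohort(cohort_config(n = 40, seed = 124))
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
  # caller RNG state untouched
  set.seed(9); u1 <- runif(1)
  set.seed(9); invisible(generate_cohort(cfg)); u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("a single-participant cohort is valid and reproducible", {
  a <- generate_cohort(cohort_config(n = 1, seed = 5))
  b <- generate_cohort(cohort_config(n = 1, seed = 5))
  expect_equal(nrow(a), 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("invalid configurations error before any sampling", {
  expect_error(cohort_config(n = 0), "n")
  expect_error(cohort_config(p_female = 1.5), "p_female")
  expect_error(cohort_config(age_band_weights = c(1, 1, 1, 1, 1) / 2),
               "sum to 1")
  expect_error(cohort_config(grip = list(sd = c(male = -1, female = 7.3))),
               "SD")
  expect_error(cohort_config(bogus_field = 1), "bogus_field")
  # slopes incompatible with the marginal SD are caught up front
  expect_error(cohort_config(grip = list(decline_per_decade =
                                           c(male = 40, female = 40))),
               "inconsistent")
})

test_that("default configuration carries the calibrated cohort moments", {
  cfg <- default_config()
  expect_equal(cfg$p_female, 0.506)
  expect_equal(unname(cfg$walk$mean["male"]), 1.04)
  expect_equal(unname(cfg$disease_prev["hypertension"]), 0.367)
  expect_equal(unname(cfg$grip$mean["male"]), 44.9)
  expect_equal(sum(cfg$age_band_weights), 1)
})

test_that("generated cohorts reproduce the configured composition and moments", {
  coh <- generate_cohort(cohort_config(n = 3000, seed = 42))
  expect_lt(abs(mean(coh$sex == "female") * 100 - 50.6), 2)

  coh5 <- generate_cohort(cohort_config(n = 5000, seed = 7))
  perf <- summarize_performance(coh5)
  m <- coh5$sex == "male"
  expect_lt(abs(mean(perf$grip_max[m], na.rm = TRUE) - 44.9), 0.5)
  expect_lt(abs(mean(perf$walk_speed[!m], na.rm = TRUE) - 0.89), 0.03)
  # age-band shares close to configured weights
  shares <- as.numeric(table(age_band(coh5$age))) / 5000
  expect_lt(max(abs(shares - default_config()$age_band_weights)), 0.02)
})

test_that("a steeper configured decline lowers mean grip in the oldest band", {
  base <- complete_config(4000, 31)
  steep <- complete_config(4000, 31,
                           grip = list(decline_per_decade = c(male = 8,
                                                              female = 6)))
  g_base <- generate_cohort(base)
  g_steep <- generate_cohort(steep)
  old_b <- age_band(g_base$age) == "80+"
  old_s <- age_band(g_steep$age) == "80+"
  pb <- summarize_performance(g_base)$grip_max
  ps <- summarize_performance(g_steep)$grip_max
  expect_lt(mean(ps[old_s], na.rm = TRUE), mean(pb[old_b], na.rm = TRUE))
})

test_that("provenance records the seed and a config hash", {
  cfg <- cohort_config(n = 10, seed = 77)
  prov <- attr(generate_cohort(cfg), "provenance")
  expect_equal(prov$seed, 77L)
  expect_match(prov$config_hash, "^[0-9a-f]{8}$")
  expect_identical(prov$config_hash, config_hash(cfg))
})

test_that("config files merge into defaults through read_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: 25", "seed: 3", "p_female: 0.4"), path)
  cfg <- read_config(path)
  expect_equal(cfg$n, 25L)
  expect_equal(cfg$p_female, 0.4)
  expect_equal(cfg$ref_age, default_config()$ref_age)
})
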