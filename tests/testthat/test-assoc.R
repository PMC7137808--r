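test_that("the Fisher switch is a pure function of the observed cells", {
  hom <- matrix(10, 2, 2)
  res <- chi2_or_fisher(hom)
  expect_equal(res$test, "Pearson chi-squared")
  expect_equal(res$estimate, 0)
  expect_equal(res$p, 1)

  with5 <- matrix(c(5, 20, 30, 40), 2, 2)
  expect_equal(chi2_or_fisher(with5)$test, "Fisher exact")
  with6 <- matrix(c(6, 20, 30, 40), 2, 2)
  expect_equal(chi2_or_fisher(with6)$test, "Pearson chi-squared")

  expect_error(chi2_or_fisher(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "margin")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  tabs <- list(matrix(c(3, 7, 8, 2), 2, 2),
               matrix(c(1, 9, 9, 1), 2, 2),
               matrix(c(5, 5, 5, 5), 2, 2),
               matrix(c(2, 14, 3, 1), 2, 2))
  for (tab in tabs) {
    res <- chi2_or_fisher(tab)
    expect_equal(res$test, "Fisher exact")
    expect_equal(res$p, fisher_oracle(tab), tolerance = 1e-9)
  }
})

test_that("trend test: null, published worked example, and 2-group identity", {
  # exactly equal proportions: no trend
  expect_equal(trend_test(c(10, 20, 30), c(100, 200, 300))$p, 1)
  expect_equal(trend_test(c(0, 0), c(10, 10))$p, 1)

  # ADL difficulty-walking counts across non-frail/prefrail/frail
  res <- trend_test(c(216, 337, 119), c(1270, 1324, 212))
  expect_lt(res$p, 0.001)

  # two groups: statistic is exactly (N-1)/N times Pearson chi-square
  ev <- c(12, 30); tot <- c(80, 70)
  tab <- rbind(tot - ev, ev)
  chi <- suppressWarnings(chisq.test(t(tab), correct = FALSE))$statistic
  N <- sum(tot)
  expect_equal(trend_test(ev, tot)$estimate,
               unname(chi) * (N - 1) / N, tolerance = 1e-12)
})

test_that("crude odds ratio: cross-product, Haldane correction, bootstrap CI", {
  expect_equal(crude_or(matrix(10, 2, 2))$estimate, 1)
  # rows = exposure, cols = outcome: OR = (20*20)/(10*10)
  expect_equal(crude_or(matrix(c(20, 10, 10, 20), 2, 2))$estimate, 4)

  zero <- matrix(c(0, 10, 10, 10), 2, 2)
  res0 <- crude_or(zero)
  expect_true(is.finite(res0$estimate) && res0$estimate > 0)

  # Woolf CI close to a bootstrap percentile CI
  tab <- matrix(c(50, 25, 30, 60), 2, 2)
  res <- crude_or(tab)
  set.seed(77)
  n <- sum(tab)
  cells <- rep(1:4, times = as.vector(tab))
  boot <- replicate(1e4, {
    t2 <- tabulate(sample(cells, n, replace = TRUE), nbins = 4)
    t2 <- matrix(t2, 2, 2) + ifelse(any(t2 == 0), 0.5, 0)
    (t2[2, 2] * t2[1, 1]) / (t2[2, 1] * t2[1, 2])
  })
  bci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(res$conf_low / bci[1] - 1), 0.1)
  expect_lt(abs(res$conf_high / bci[2] - 1), 0.1)
})

test_that("an unadjusted logistic OR equals the crude cross-product", {
  set.seed(15)
  for (rep in 1:5) {
    n <- 400
    x <- runif(n) < 0.4
    y <- runif(n) < plogis(-1.2 + 0.8 * x)
    tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
    res <- adjusted_or(y, x, covariates = NULL)
    expect_equal(res$or_table$or,
                 unname((tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])),
                 tolerance = 1e-6)
  }
})

test_that("separation is reported as non-estimable, not as a divergent OR", {
  y <- c(rep(FALSE, 50), rep(TRUE, 5), rep(FALSE, 20))
  x <- factor(c(rep("absent", 55), rep("present", 20)),
              levels = c("absent", "present"))
  res <- adjusted_or(y, x, covariates = NULL)
  expect_false(res$or_table$estimable[1])
  expect_true(is.na(res$or_table$or[1]))
})

test_that("frailty outcome codings exclude or merge unable-to-score", {
  cats <- c("non_frail", "prefrail", "frail", "unable_to_score")
  expect_equal(frailty_outcome(cats, "frail_only"),
               c(FALSE, FALSE, TRUE, NA))
  expect_equal(frailty_outcome(cats, "frail_or_unable"),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("group comparison: t-test and exact Mann-Whitney", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(group_compare(x, x)$p, 1)

  set.seed(8)
  a <- rnorm(100); b <- rnorm(100, 2)
  expect_lt(group_compare(a, b)$p, 0.001)

  res <- group_compare(c(1, 2, 3), c(4, 5, 6), "nonnormal")
  expect_equal(res$p, mw_oracle(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  # a non-extreme split as well
  res2 <- group_compare(c(1, 4, 6), c(2, 3, 5), "nonnormal")
  expect_equal(res2$p, mw_oracle(c(1, 4, 6), c(2, 3, 5)), tolerance = 1e-12)
})
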