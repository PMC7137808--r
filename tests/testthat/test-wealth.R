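test_that("polychoric correlation recovers independence and concordance", {
  # 2x2 with cell proportions equal to the product of the margins
  x <- rep(c(1, 1, 2, 2), times = c(3000, 1000, 4500, 1500))
  y <- rep(c(1, 2, 1, 2), times = c(3000, 1000, 4500, 1500))
  expect_lt(abs(polychoric_corr(x, y)), 0.02)

  # identical ordinal vectors with mixed margins approach rho = 1
  z <- rep(1:3, times = c(30, 50, 20))
  expect_gt(polychoric_corr(z, z), 0.95)
})

test_that("polychoric estimate matches the brute-force grid oracle", {
  tab <- matrix(c(40, 10, 10, 40), 2, 2)
  x <- rep(c(1, 1, 2, 2), times = c(40, 10, 10, 40))
  y <- rep(c(1, 2, 1, 2), times = c(40, 10, 10, 40))
  est <- polychoric_corr(x, y)
  expect_equal(est, polychoric_grid_oracle(tab), tolerance = 1e-3)

  # an asymmetric table as well
  tab2 <- matrix(c(55, 20, 8, 37), 2, 2)
  x2 <- rep(c(1, 1, 2, 2), times = tab2[cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))])
  y2 <- rep(c(1, 2, 1, 2), times = tab2[cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))])
  expect_equal(polychoric_corr(x2, y2), polychoric_grid_oracle(tab2),
               tolerance = 1e-3)
})

test_that("reversing one coding flips the sign; reversing both restores it", {
  set.seed(10)
  lat <- rnorm(300)
  x <- findInterval(0.7 * lat + rnorm(300, 0, 0.7), c(-0.5, 0.6)) + 1
  y <- findInterval(0.6 * lat + rnorm(300, 0, 0.8), c(-1, 0, 1)) + 1
  r <- polychoric_corr(x, y)
  expect_equal(polychoric_corr(max(x) + 1 - x, y), -r, tolerance = 1e-4)
  expect_equal(polychoric_corr(max(x) + 1 - x, max(y) + 1 - y), r,
               tolerance = 1e-4)
})

test_that("empty ordinal categories are collapsed with a warning", {
  x <- factor(rep(c(1, 3), each = 30), levels = 1:3)
  y <- rep(c(1, 2), each = 30)
  expect_warning(r <- polychoric_corr(x, y), "collapsing")
  expect_true(abs(r) <= 0.999)
})

test_that("two perfectly correlated binary assets load symmetrically", {
  a <- rep(c(1, 2), times = c(60, 40))
  wi <- wealth_index(data.frame(asset_a = a, asset_b = a), anchor = "asset_a")
  expect_equal(abs(unname(wi$loadings[1])), abs(unname(wi$loadings[2])),
               tolerance = 1e-8)
  expect_gt(wi$loadings["asset_a"], 0)
})

test_that("the index recovers a latent wealth factor", {
  # the default 12-item battery generated from one latent factor
  set.seed(22)
  n <- 2000
  w <- rnorm(n)
  items <- default_config()$assets
  df <- as.data.frame(lapply(items, function(it)
    findInterval(it$loading * w + sqrt(1 - it$loading^2) * rnorm(n),
                 qnorm(it$cum)) + 1L))
  wi <- wealth_index(df)
  expect_gt(cor(wi$scores, w, method = "spearman"), 0.8)
  # higher score must mean wealthier (electricity anchored positive)
  expect_gt(wi$loadings["asset_electricity"], 0)
})

test_that("quintiles partition scores into equal fifths", {
  set.seed(33)
  n <- 1000
  w <- rnorm(n)
  items <- default_config()$assets
  df <- as.data.frame(lapply(items, function(it)
    findInterval(it$loading * w + sqrt(1 - it$loading^2) * rnorm(n),
                 qnorm(it$cum)) + 1L))
  wi <- wealth_index(df)
  expect_true(all(is.finite(wi$scores)))
  expect_equal(as.numeric(table(wi$quintile)), rep(200, 5))
})

test_that("the index is invariant (up to sign anchoring) to item order", {
  coh <- generate_cohort(cohort_config(n = 400, seed = 19))
  cols <- grep("^asset_", names(coh), value = TRUE)
  df <- as.data.frame(coh)[cols]
  wi1 <- wealth_index(df, anchor = "asset_electricity")
  wi2 <- wealth_index(df[rev(cols)], anchor = "asset_electricity")
  expect_equal(wi1$scores, wi2$scores, tolerance = 1e-6)
  expect_equal(wi1$quintile, wi2$quintile)
})
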