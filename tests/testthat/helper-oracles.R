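# Independent oracles: brute-force or closed-form routes kept deliberately
# separate from the package implementation paths they check.

# Fisher exact two-sided p for a 2x2 table by exhaustive hypergeometric
# enumeration over all tables with the observed margins (probabilities not
# exceeding the observed one, with the conventional 1+1e-7 slack).
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all rank splits
# (no-ties samples, small n), mirroring the doubled-tail convention.
mw_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  ws <- apply(splits, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  cdf_le <- mean(ws <= w_obs)
  cdf_ge <- mean(ws >= w_obs)
  min(1, 2 * min(cdf_le, cdf_ge))
}

# Bivariate normal CDF by a route independent of the package's
# (one-dimensional conditioning integral over the first coordinate).
pbinorm_oracle <- function(h, k, rho) {
  if (!is.finite(h)) return(if (h > 0) stats::pnorm(k) else 0)
  if (!is.finite(k)) return(if (k > 0) stats::pnorm(h) else 0)
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((k - rho * x) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, h, rel.tol = 1e-10)$value
}

# Polychoric rho for a 2x2 table by grid search over rho, cell
# probabilities via pbinorm_oracle, thresholds from the margins.
polychoric_grid_oracle <- function(tab, step = 5e-4) {
  a <- stats::qnorm(sum(tab[1, ]) / sum(tab))
  b <- stats::qnorm(sum(tab[, 1]) / sum(tab))
  grid <- seq(-0.999, 0.999, by = step)
  ll <- vapply(grid, function(r) {
    p11 <- pbinorm_oracle(a, b, r)
    prow <- stats::pnorm(a); pcol <- stats::pnorm(b)
    # column-major: [1,1], [2,1] = P(X>a, Y<=b), [1,2] = P(X<=a, Y>b), [2,2]
    p <- c(p11, pcol - p11, prow - p11, 1 - prow - pcol + p11)
    sum(tab * log(pmax(p, 1e-12)))
  }, numeric(1))
  grid[which.max(ll)]
}

# OLS slope by the closed-form covariance formula.
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Type-7 quantile by explicit sort-and-interpolate indexing.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
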