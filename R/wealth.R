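# Asset-based wealth index: polychoric correlations, first principal
# component, quintiles.

# Standard bivariate normal CDF P(X <= h, Y <= k) with correlation rho,
# via the single-integral identity
#   Phi2(h, k; rho) = Phi(h) Phi(k)
#     + (1/2pi) * int_0^{asin(rho)} exp(-(h^2 - 2 h k sin t + k^2)
#                                        / (2 cos^2 t)) dt,
# evaluated with adaptive quadrature.  Accurate to ~1e-10, ample for
# threshold-based likelihoods.
pbinorm <- function(h, k, rho) {
  if (h == Inf && k == Inf) return(1)
  if (h == -Inf || k == -Inf) return(0)
  if (h == Inf) return(stats::pnorm(k))
  if (k == Inf) return(stats::pnorm(h))
  if (abs(rho) >= 1) {
    rho <- sign(rho)
    return(if (rho > 0) stats::pnorm(min(h, k))
           else max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  }
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  f <- function(t) exp(-(h^2 - 2 * h * k * sin(t) + k^2) / (2 * cos(t)^2))
  base + stats::integrate(f, 0, asin(rho), rel.tol = 1e-10)$value / (2 * pi)
}

# Cell probabilities of a two-way ordinal table under the bivariate normal
# model with row thresholds a, column thresholds b (each including -Inf, Inf).
binorm_cells <- function(a, b, rho) {
  R <- length(a) - 1; C <- length(b) - 1
  cdf <- matrix(0, R + 1, C + 1)
  for (i in seq_len(R + 1)) for (j in seq_len(C + 1))
    cdf[i, j] <- pbinorm(a[i], b[j], rho)
  p <- cdf[-1, -1, drop = FALSE] - cdf[-(R + 1), -1, drop = FALSE] -
       cdf[-1, -(C + 1), drop = FALSE] + cdf[-(R + 1), -(C + 1), drop = FALSE]
  pmax(p, 1e-12)
}

# Thresholds from marginal cumulative proportions (step one of the
# two-step estimator).
marginal_thresholds <- function(counts) {
  cum <- cumsum(counts) / sum(counts)
  c(-Inf, stats::qnorm(cum[-length(cum)]), Inf)
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step maximum-likelihood estimator of the correlation of the latent
#' bivariate normal generating a cross-tabulation of two ordinal items:
#' thresholds are fixed at the inverse-normal transforms of the marginal
#' proportions, then the correlation maximising the multinomial cell
#' likelihood is found by one-dimensional optimisation, bounded in
#' \[-0.999, 0.999\] for stability.  Empty categories are collapsed with a
#' warning.
#'
#' @param x,y integer/ordered vectors (pairwise-complete cases are used;
#'   at least 20 required, each variable with at least 2 observed
#'   categories).
#' @return the estimated correlation (scalar).
#' @export
polychoric_corr <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  pf_assert(sum(keep) >= 20, "need >= 20 complete pairs, have %d", sum(keep))
  as_cat <- function(v) {
    if (is.factor(v)) return(v)
    if (is.numeric(v) && all(v == round(v)))
      return(factor(v, levels = min(v):max(v)))  # keep gaps visible
    factor(v)
  }
  tab <- table(as_cat(x[keep]), as_cat(y[keep]))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("collapsing empty ordinal categories")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  pf_assert(nrow(tab) >= 2 && ncol(tab) >= 2,
            "both variables need >= 2 observed categories")
  polychoric_from_table(tab)
}

# Core estimator on a contingency table of ordinal categories.
polychoric_from_table <- function(tab) {
  a <- marginal_thresholds(rowSums(tab))
  b <- marginal_thresholds(colSums(tab))
  negll <- function(rho) -sum(tab * log(binorm_cells(a, b, rho)))
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-6)
  opt$minimum
}

# Polychoric correlation matrix of an ordinal data frame.
polychoric_matrix <- function(assets) {
  k <- ncol(assets)
  rho <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- suppressWarnings(polychoric_corr(assets[[i]], assets[[j]]))
    rho[i, j] <- rho[j, i] <- r
  }
  dimnames(rho) <- list(names(assets), names(assets))
  rho
}

# Repair a symmetric matrix to positive semi-definiteness by clipping
# eigenvalues at a small floor, then restoring unit diagonal.
psd_repair <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) return(list(m = m, repaired = FALSE))
  v <- pmax(e$values, floor)
  out <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / (d %o% d)
  dimnames(out) <- dimnames(m)
  list(m = out, repaired = TRUE)
}

# Conditional means of a standard normal within threshold intervals:
# E[Z | tau_{c-1} < Z <= tau_c] for each category c.
category_normal_scores <- function(counts) {
  tau <- marginal_thresholds(counts)
  lo <- tau[-length(tau)]; hi <- tau[-1]
  p <- stats::pnorm(hi) - stats::pnorm(lo)
  (stats::dnorm(lo) - stats::dnorm(hi)) / pmax(p, 1e-12)
}

#' Asset-based wealth index via polychoric principal components
#'
#' Estimates the polychoric correlation matrix of the ordinal asset items,
#' repairs it to positive semi-definiteness if needed (eigenvalue clipping
#' at 1e-6), and scores each participant on the first eigenvector.  Ordinal
#' responses enter as their category mean normal scores, so the score is the
#' first principal component of the latent item scale.  The eigenvector sign
#' is anchored so that the `anchor` item (electricity by default, presence =
#' wealthier) loads positively.  Quintiles (1 = poorest) use the same
#' quantile rule as the frailty cutoffs.
#'
#' @param assets data frame of ordinal items (integer codes ordered by
#'   presumed wealth), or a `cohort` whose `asset_*` columns are used.
#' @param anchor name of the sign-anchor item; defaults to the first column
#'   matching "electric", else the first column.
#' @param quantile_type quantile rule (default 7).
#' @return a `wealth_index` object: `scores`, `quintile`, `loadings`,
#'   `rho` (polychoric matrix), `repaired`, `prop_var`.
#' @export
wealth_index <- function(assets, anchor = NULL, quantile_type = 7) {
  id <- NULL
  if (inherits(assets, "cohort")) {
    id <- assets$id
    cols <- grep("^asset_", names(assets), value = TRUE)
    pf_assert(length(cols) >= 2, "cohort has fewer than 2 asset_* columns")
    assets <- as.data.frame(assets)[cols]
  }
  assets <- as.data.frame(assets)
  pf_assert(ncol(assets) >= 2, "need at least 2 asset items")
  rho <- polychoric_matrix(assets)
  rep_ <- psd_repair(rho)
  e <- eigen(rep_$m, symmetric = TRUE)
  if (any(!is.finite(e$values)))
    stop("eigen-decomposition of the polychoric matrix failed", call. = FALSE)
  v <- e$vectors[, 1]
  names(v) <- colnames(rho)
  if (is.null(anchor)) {
    hit <- grep("electric", names(v), value = TRUE)
    anchor <- if (length(hit)) hit[1] else names(v)[1]
  }
  pf_assert(anchor %in% names(v), "anchor item '%s' not found", anchor)
  if (v[anchor] < 0) v <- -v

  # per-item normal scores; a missing item contributes the item mean (zero)
  z <- matrix(0, nrow(assets), ncol(assets))
  for (j in seq_len(ncol(assets))) {
    xj <- factor(assets[[j]])
    sc <- category_normal_scores(as.numeric(table(xj)))
    z[, j] <- ifelse(is.na(xj), 0, sc[as.integer(xj)])
  }
  scores <- drop(z %*% v)
  qs <- pf_quantile(scores, c(0.2, 0.4, 0.6, 0.8), type = quantile_type)
  quintile <- findInterval(scores, qs, left.open = TRUE) + 1L

  structure(list(id = id, scores = scores, quintile = quintile,
                 loadings = v, rho = rho, repaired = rep_$repaired,
                 prop_var = e$values[1] / sum(e$values),
                 thresholds = lapply(assets, function(x)
                   marginal_thresholds(as.numeric(table(factor(x)))))),
            class = "wealth_index")
}

#' @export
print.wealth_index <- function(x, ...) {
  cat(sprintf("Polychoric-PCA wealth index: %d participants, %d items\n",
              length(x$scores), length(x$loadings)))
  cat(sprintf("  first component explains %.1f%% of latent variance%s\n",
              100 * x$prop_var,
              if (x$repaired) " (correlation matrix PSD-repaired)" else ""))
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Write wealth-index loadings and thresholds as JSON for audit
#'
#' @param wi a `wealth_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wealth_audit <- function(wi, path) {
  pf_assert(inherits(wi, "wealth_index"), "expected a wealth_index")
  jsonlite::write_json(
    list(loadings = as.list(wi$loadings),
         prop_var = wi$prop_var, repaired = wi$repaired,
         thresholds = lapply(wi$thresholds, function(t)
           t[is.finite(t)])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
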