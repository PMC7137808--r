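# Association battery: contingency tests with the Fisher switch rule,
# Mantel-Haenszel linear trend, crude and adjusted logistic odds ratios,
# and two-group comparisons.

new_assoc_result <- function(estimate, ci = c(NA_real_, NA_real_),
                             p, test, n, coding = NA_character_,
                             extra = list()) {
  structure(c(list(estimate = estimate, conf_low = ci[1], conf_high = ci[2],
                   p = p, test = test, n = n, coding = coding), extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s (n = %d%s)\n", x$test, x$n,
              if (!is.na(x$coding)) paste0(", coding = ", x$coding) else ""))
  if (!is.null(x$or_table)) {
    print(x$or_table, row.names = FALSE, digits = 3)
  } else {
    if (is.finite(x$estimate))
      cat(sprintf("  estimate = %.4g", x$estimate))
    if (is.finite(x$conf_low))
      cat(sprintf("  [%.4g, %.4g]", x$conf_low, x$conf_high))
    cat(sprintf("  p = %.4g\n", x$p))
  }
  invisible(x)
}

#' Chi-squared test with the small-cell Fisher switch
#'
#' Pearson's chi-squared test (without continuity correction), switching to
#' Fisher's exact test whenever any observed cell is five or less.  The
#' switch is a pure function of the observed counts.
#'
#' @param tab integer matrix of counts (2x2 or r x c).
#' @return an `assoc_result` with the statistic (chi-squared branch) or the
#'   conditional odds ratio (Fisher branch, 2x2 only), the p-value and the
#'   test name.
#' @export
chi2_or_fisher <- function(tab) {
  tab <- as.matrix(tab)
  pf_assert(all(tab >= 0) && sum(tab) > 0, "counts must be non-negative, total > 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table", call. = FALSE)
  n <- sum(tab)
  if (any(tab <= 5)) {
    ft <- stats::fisher.test(tab, workspace = 2e7)
    est <- if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_
    ci <- if (!is.null(ft$conf.int)) ft$conf.int else c(NA_real_, NA_real_)
    new_assoc_result(est, ci, ft$p.value, "Fisher exact", n,
                     extra = list(table = tab))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    new_assoc_result(unname(ct$statistic), p = ct$p.value,
                     test = "Pearson chi-squared", n = n,
                     extra = list(df = unname(ct$parameter), table = tab))
  }
}

#' Mantel-Haenszel test for linear trend
#'
#' One-degree-of-freedom chi-squared test for a linear trend in a binary
#' outcome across ordered groups, using equally spaced integer scores and
#' the (N-1)-variance form: the statistic is (N-1) times the squared
#' Pearson correlation between group score and outcome over the N subjects.
#'
#' @param events number of outcome-positive subjects per ordered group.
#' @param totals group sizes.
#' @param scores group scores (default 0, 1, 2, ...).
#' @return an `assoc_result`; when the outcome does not vary at all the
#'   statistic is 0 and p = 1.
#' @export
trend_test <- function(events, totals, scores = seq_along(events) - 1) {
  pf_assert(length(events) == length(totals) && length(events) >= 2,
            "need events and totals for >= 2 ordered groups")
  pf_assert(all(events >= 0 & events <= totals), "events must be in [0, totals]")
  N <- sum(totals)
  E <- sum(events)
  if (E == 0 || E == N)
    return(new_assoc_result(0, p = 1, test = "Mantel-Haenszel trend", n = N))
  xbar <- sum(scores * totals) / N
  pbar <- E / N
  sxy <- sum(scores * events) - xbar * E
  sxx <- sum(totals * (scores - xbar)^2)
  syy <- N * pbar * (1 - pbar)
  if (sxx == 0)
    return(new_assoc_result(0, p = 1, test = "Mantel-Haenszel trend", n = N))
  r2 <- sxy^2 / (sxx * syy)
  stat <- (N - 1) * r2
  new_assoc_result(stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
                   test = "Mantel-Haenszel trend", n = N,
                   extra = list(df = 1))
}

#' Crude odds ratio of a 2x2 table
#'
#' Cross-product odds ratio with the Woolf log-scale 95% confidence
#' interval; when any cell is zero the Haldane-Anscombe correction (+0.5 to
#' every cell) is applied first.
#'
#' @param tab 2x2 matrix: rows = exposure (unexposed first), columns =
#'   outcome (negative first).
#' @return an `assoc_result` with the odds ratio and Wald/Woolf CI.
#' @export
crude_or <- function(tab) {
  tab <- as.matrix(tab)
  pf_assert(all(dim(tab) == c(2, 2)), "crude_or() needs a 2x2 table")
  t2 <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (t2[2, 2] * t2[1, 1]) / (t2[2, 1] * t2[1, 2])
  se <- sqrt(sum(1 / t2))
  z <- stats::qnorm(0.975)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  new_assoc_result(or, ci, p, "crude odds ratio (Woolf CI)", sum(tab),
                   extra = list(table = tab, corrected = any(tab == 0)))
}

#' Frailty outcome coding
#'
#' Converts frailty categories to the binary outcome under the two
#' sensitivity codings: `frail_only` treats frail as positive and excludes
#' unable-to-score records (`NA`); `frail_or_unable` merges unable-to-score
#' with frail.
#'
#' @param category factor/character of categories (`non_frail`, `prefrail`,
#'   `frail`, `unable_to_score`).
#' @param coding `"frail_only"` or `"frail_or_unable"`.
#' @return logical vector.
#' @export
frailty_outcome <- function(category, coding = c("frail_only", "frail_or_unable")) {
  coding <- match.arg(coding)
  category <- as.character(category)
  if (coding == "frail_only")
    ifelse(category == "unable_to_score", NA, category == "frail")
  else
    category %in% c("frail", "unable_to_score") & !is.na(category)
}

#' Adjusted odds ratios by logistic regression
#'
#' Maximum-likelihood binary logistic regression of an outcome on a
#' categorical or binary exposure plus covariates (age in years and sex by
#' convention).  Returns one odds ratio per non-reference exposure level
#' with Wald 95% confidence intervals.  Levels affected by separation (no
#' outcome variation, divergent estimate or exploding standard error) are
#' reported as non-estimable (`NA` with `estimable = FALSE`) rather than as
#' divergent numbers.
#'
#' @param outcome logical vector (records with `NA` outcome are dropped,
#'   which is how the `frail_only` coding excludes unable-to-score records).
#' @param exposure factor (first level = reference) or logical/binary.
#' @param covariates data frame of adjustment covariates (or `NULL` for a
#'   crude model).
#' @param coding label recorded in the result (e.g. the frailty coding).
#' @return an `assoc_result` whose `or_table` has one row per non-reference
#'   level: `level`, `or`, `conf_low`, `conf_high`, `p`, `estimable`.
#' @export
adjusted_or <- function(outcome, exposure, covariates = NULL,
                        coding = NA_character_) {
  if (is.logical(exposure) || (is.numeric(exposure) && all(exposure %in% c(0, 1, NA))))
    exposure <- factor(as.logical(exposure), levels = c(FALSE, TRUE),
                       labels = c("no", "yes"))
  exposure <- droplevels(as.factor(exposure))
  df <- data.frame(.y = as.logical(outcome), .x = exposure)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    pf_assert(nrow(covariates) == length(outcome),
              "covariates must have one row per outcome")
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.x <- droplevels(df$.x)
  n <- nrow(df)
  pf_assert(n > 0, "no complete cases")
  pf_assert(nlevels(df$.x) >= 2, "exposure has a single observed level")

  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  lev <- levels(df$.x)[-1]
  rows <- paste0(".x", lev)
  z <- stats::qnorm(0.975)
  out <- data.frame(level = lev, or = NA_real_, conf_low = NA_real_,
                    conf_high = NA_real_, p = NA_real_, estimable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rows)) {
    # separation guard: a level with zero outcome variation, or a divergent
    # fit, is reported as non-estimable
    sub <- df$.y[df$.x == lev[i]]
    degenerate <- length(sub) == 0 || all(sub) || !any(sub)
    if (!rows[i] %in% rownames(cf)) next
    b <- cf[rows[i], "Estimate"]; se <- cf[rows[i], "Std. Error"]
    if (degenerate || !is.finite(b) || abs(b) > 15 || se > 15) next
    out$or[i] <- exp(b)
    out$conf_low[i] <- exp(b - z * se)
    out$conf_high[i] <- exp(b + z * se)
    out$p[i] <- cf[rows[i], "Pr(>|z|)"]
    out$estimable[i] <- TRUE
  }
  new_assoc_result(if (nrow(out) == 1) out$or else NA_real_,
                   ci = if (nrow(out) == 1)
                     c(out$conf_low, out$conf_high) else c(NA_real_, NA_real_),
                   p = if (nrow(out) == 1) out$p else NA_real_,
                   test = if (is.null(covariates)) "logistic (crude)"
                          else "logistic (adjusted)",
                   n = n, coding = coding,
                   extra = list(or_table = out, model = fit))
}

#' Two-group comparison of a continuous variable
#'
#' Student's t-test for normally distributed variables, Mann-Whitney U test
#' otherwise (exact when sample sizes permit and no ties), two-sided.
#'
#' @param x,y numeric samples for the two groups.
#' @param distribution `"normal"` (t-test) or `"nonnormal"` (Mann-Whitney).
#' @return an `assoc_result` with statistic and p-value.
#' @export
group_compare <- function(x, y, distribution = c("normal", "nonnormal")) {
  distribution <- match.arg(distribution)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  pf_assert(length(x) >= 2 && length(y) >= 2, "need >= 2 values per group")
  if (distribution == "normal") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
      return(new_assoc_result(0, p = 1, test = "Student t",
                              n = length(x) + length(y)))
    tt <- stats::t.test(x, y)
    new_assoc_result(unname(tt$statistic), p = tt$p.value, test = "Student t",
                     n = length(x) + length(y))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE))
    new_assoc_result(unname(wt$statistic), p = wt$p.value,
                     test = "Mann-Whitney U", n = length(x) + length(y))
  }
}
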