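# End-to-end orchestration: score, classify, index, associate, and emit the
# publication-style summary tables with one-decimal half-up rounding and
# numerator/denominator bookkeeping in every percentage cell.

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one cohort: performance aggregation, frailty
#' scoring (derive- or fixed-mode cutoffs), clinical classification, the
#' wealth index (when `asset_*` columns are present), and the association
#' battery under both frailty codings.  Deterministic: the same serialized
#' cohort reproduces the bundle exactly.
#'
#' @param cohort a `cohort`.
#' @param mode `"derive"` or `"fixed"`.
#' @param cutoffs [cutoff_set()] for fixed mode.
#' @param strict_missing missing-domain rule, see [score_frailty()].
#' @param quantile_type quantile rule (default 7).
#' @return a `report_bundle`: a list of data frames (`baseline`,
#'   `components`, `categories`, `domains_by_age_sex`, `adl_by_category`,
#'   `performance_by_adl`, `associations`, `multivariable`, `ewgsop`) plus
#'   `fit`, `clinical`, `wealth` and `provenance`.
#' @export
run_pipeline <- function(cohort, mode = c("derive", "fixed"), cutoffs = NULL,
                         strict_missing = TRUE, quantile_type = 7) {
  mode <- match.arg(mode)
  pf_assert(inherits(cohort, "cohort"), "expected a cohort")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  fit <- stage("frailty_score",
               score_cohort(cohort, mode, cutoffs,
                            strict_missing = strict_missing,
                            quantile_type = quantile_type))
  perf <- fit$performance
  clin <- stage("clinical_classifiers", clinical_profile(cohort, perf))
  has_assets <- length(grep("^asset_", names(cohort))) >= 2
  wealth <- if (has_assets) stage("wealth_index", wealth_index(cohort))
            else NULL

  sfit <- summary(fit)
  bundle <- list(
    baseline = stage("baseline_table",
                     .baseline_table(cohort, perf, clin)),
    components = sfit$components,
    categories = sfit$categories,
    domains_by_age_sex = stage("domain_grid", .domain_grid(cohort, fit)),
    adl_by_category = stage("adl_by_category",
                            .adl_by_category(clin, fit)),
    performance_by_adl = stage("performance_by_adl",
                               .performance_by_adl(cohort, perf, clin)),
    associations = stage("associations",
                         .association_table(cohort, fit, clin, wealth)),
    multivariable = stage("multivariable",
                          .multivariable_table(cohort, fit, clin, wealth)),
    ewgsop = stage("ewgsop_block", .ewgsop_block(cohort, perf)),
    fit = fit, clinical = clin, wealth = wealth,
    provenance = list(n = nrow(cohort),
                      mode = mode,
                      cutoffs = coef(fit),
                      cohort_provenance = attr(cohort, "provenance")))
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> n = %d (%s-mode cutoffs)\n",
              x$provenance$n, x$provenance$mode))
  cat("Frailty categories:\n")
  print(x$categories, row.names = FALSE)
  cat("\nComponents:\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

.pct_row <- function(num, den) {
  data.frame(n = num, den = den, percent = format_percent(num, den))
}

.baseline_table <- function(cohort, perf, clin) {
  n <- nrow(cohort)
  band <- age_band(cohort$age)
  rows <- list()
  add <- function(field, group, num, den)
    rows[[length(rows) + 1]] <<- cbind(
      data.frame(field = field, group = group, stringsAsFactors = FALSE),
      .pct_row(num, den))
  for (b in levels(band)) add("age_band", b, sum(band == b, na.rm = TRUE), n)
  add("female_sex", "", sum(cohort$sex == "female", na.rm = TRUE), n)
  add("diabetes", "", sum(isTRUE_v(clin$diabetes)), n)
  add("hypertension", "", sum(isTRUE_v(clin$hypertension)), n)
  for (d in c("cancer", "tb", "hiv", "respiratory", "stroke", "heart"))
    add(d, "", sum(isTRUE_v(clin[[d]])), n)
  if ("marital" %in% names(cohort)) {
    for (lev in .pf_marital_levels)
      add("marital", lev, sum(cohort$marital == lev, na.rm = TRUE), n)
    add("marital", "missing", sum(is.na(cohort$marital)), n)
  }
  add("any_adl_impairment", "", sum(isTRUE_v(clin$any_adl)), n)
  counts <- do.call(rbind, rows)

  msd <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  qiqr <- function(v) stats::quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE,
                                      names = FALSE)
  meas <- list()
  for (s in c("male", "female")) {
    i <- !is.na(cohort$sex) & cohort$sex == s
    for (m in c("bmi", "walk_speed", "grip_max")) {
      v <- if (m == "bmi") cohort$bmi[i]
           else perf[[m]][i]
      st <- msd(v)
      meas[[length(meas) + 1]] <- data.frame(
        measure = m, sex = s, mean = st["mean"], sd = st["sd"],
        median = NA_real_, q1 = NA_real_, q3 = NA_real_, row.names = NULL)
    }
    q <- qiqr(perf$chair_time[i])
    meas[[length(meas) + 1]] <- data.frame(
      measure = "chair_time", sex = s, mean = NA_real_, sd = NA_real_,
      median = q[1], q1 = q[2], q3 = q[3], row.names = NULL)
  }
  sit <- msd(cohort$sitting_hours)
  meas[[length(meas) + 1]] <- data.frame(
    measure = "sitting_hours", sex = "all", mean = sit["mean"], sd = sit["sd"],
    median = NA_real_, q1 = NA_real_, q3 = NA_real_, row.names = NULL)
  list(counts = counts, measures = do.call(rbind, meas))
}

.domain_grid <- function(cohort, fit) {
  band <- age_band(cohort$age)
  comp <- c("low_grip", "low_walk", "weight_loss", "exhaustion", "low_activity")
  out <- list()
  for (b in levels(band)) for (s in c("male", "female")) {
    i <- !is.na(band) & band == b & !is.na(cohort$sex) & cohort$sex == s
    for (cm in comp) {
      v <- fit$scores[[cm]][i]
      out[[length(out) + 1]] <- cbind(
        data.frame(age_band = b, sex = s, component = cm,
                   stringsAsFactors = FALSE),
        .pct_row(sum(v, na.rm = TRUE), sum(!is.na(v))))
    }
  }
  do.call(rbind, out)
}

.adl_by_category <- function(clin, fit) {
  cat_levels <- c("non_frail", "prefrail", "frail", "unable_to_score")
  items <- c("any_adl", .adl_items)
  out <- list()
  for (item in items) {
    v <- clin[[item]]
    row <- data.frame(adl = item, stringsAsFactors = FALSE)
    for (cl in cat_levels) {
      i <- fit$scores$category == cl
      row[[paste0(cl, "_n")]] <- sum(v[i], na.rm = TRUE)
      row[[paste0(cl, "_den")]] <- sum(i)
      row[[paste0(cl, "_pct")]] <- format_percent(sum(v[i], na.rm = TRUE), sum(i))
    }
    # trend across the three scoreable categories only
    ev <- sapply(cat_levels[1:3], function(cl)
      sum(v[fit$scores$category == cl], na.rm = TRUE))
    tot <- sapply(cat_levels[1:3], function(cl)
      sum(!is.na(v) & fit$scores$category == cl))
    row$p_trend <- trend_test(ev, tot)$p
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}

.performance_by_adl <- function(cohort, perf, clin) {
  items <- c("any_adl", .adl_items)
  out <- list()
  for (item in items) for (s in c("male", "female")) {
    sx <- !is.na(cohort$sex) & cohort$sex == s
    imp <- clin[[item]]
    for (yes in c(FALSE, TRUE)) {
      i <- sx & !is.na(imp) & imp == yes
      q <- stats::quantile(perf$chair_time[i], c(0.5, 0.25, 0.75),
                           na.rm = TRUE, names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        adl = item, sex = s, impaired = yes, n = sum(i),
        walk_mean = mean(perf$walk_speed[i], na.rm = TRUE),
        walk_sd = stats::sd(perf$walk_speed[i], na.rm = TRUE),
        grip_mean = mean(perf$grip_max[i], na.rm = TRUE),
        grip_sd = stats::sd(perf$grip_max[i], na.rm = TRUE),
        chair_median = q[1], chair_q1 = q[2], chair_q3 = q[3],
        stringsAsFactors = FALSE)
    }
    i0 <- sx & isTRUE_v(!imp); i1 <- sx & isTRUE_v(imp)
    pw <- tryCatch(group_compare(perf$walk_speed[i1], perf$walk_speed[i0])$p,
                   error = function(e) NA_real_)
    pg <- tryCatch(group_compare(perf$grip_max[i1], perf$grip_max[i0])$p,
                   error = function(e) NA_real_)
    pc <- tryCatch(group_compare(perf$chair_time[i1], perf$chair_time[i0],
                                 "nonnormal")$p,
                   error = function(e) NA_real_)
    k <- length(out)
    out[[k]]$p_walk <- pw; out[[k]]$p_grip <- pg; out[[k]]$p_chair <- pc
    out[[k - 1]]$p_walk <- NA; out[[k - 1]]$p_grip <- NA; out[[k - 1]]$p_chair <- NA
  }
  do.call(rbind, out)
}

# bivariate (chi-square/Fisher) p and age/sex-adjusted ORs for one
# categorical exposure under one frailty coding
.one_association <- function(exposure_name, exposure, outcome, age, sex,
                             coding) {
  if (is.logical(exposure))
    exposure <- factor(exposure, levels = c(FALSE, TRUE),
                       labels = c("no", "yes"))
  keep <- !is.na(outcome) & !is.na(exposure) & !is.na(age) & !is.na(sex)
  y <- outcome[keep]; x <- droplevels(as.factor(exposure[keep]))
  if (nlevels(x) < 2 || length(unique(y)) < 2) return(NULL)
  tab <- table(x, factor(y, levels = c(FALSE, TRUE)))
  biv <- tryCatch(chi2_or_fisher(tab), error = function(e) NULL)
  adj <- adjusted_or(y, x, data.frame(age = age[keep], sex = sex[keep]),
                     coding = coding)
  ot <- adj$or_table
  lev <- levels(x)
  out <- data.frame(exposure = exposure_name, level = lev,
                    events = as.numeric(tab[, "TRUE"]),
                    total = as.numeric(rowSums(tab)),
                    stringsAsFactors = FALSE)
  out$percent <- format_percent(out$events, out$total)
  out$p_bivariate <- if (is.null(biv)) NA_real_ else biv$p
  out$bivariate_test <- if (is.null(biv)) NA_character_ else biv$test
  idx <- match(out$level, ot$level)
  out$or <- ot$or[idx]; out$conf_low <- ot$conf_low[idx]
  out$conf_high <- ot$conf_high[idx]; out$p_adjusted <- ot$p[idx]
  out$estimable <- ot$estimable[idx]
  out$or[out$level == lev[1]] <- 1
  out$estimable[out$level == lev[1]] <- NA
  out$coding <- coding
  out
}

.association_table <- function(cohort, fit, clin, wealth) {
  out <- list()
  for (coding in c("frail_only", "frail_or_unable")) {
    y <- frailty_outcome(fit$scores$category, coding)
    if ("marital" %in% names(cohort))
      out[[length(out) + 1]] <- .one_association(
        "marital", factor(cohort$marital, levels = .pf_marital_levels),
        y, cohort$age, cohort$sex, coding)
    if (!is.null(wealth))
      out[[length(out) + 1]] <- .one_association(
        "wealth_quintile", factor(wealth$quintile, levels = 1:5),
        y, cohort$age, cohort$sex, coding)
    for (d in c("diabetes", "hypertension", "cancer", "tb", "hiv",
                "respiratory", "stroke", "heart"))
      out[[length(out) + 1]] <- .one_association(
        d, clin[[d]], y, cohort$age, cohort$sex, coding)
  }
  do.call(rbind, out)
}

.multivariable_table <- function(cohort, fit, clin, wealth) {
  out <- list()
  for (coding in c("frail_only", "frail_or_unable")) {
    y <- frailty_outcome(fit$scores$category, coding)
    df <- data.frame(.y = y, age = cohort$age,
                     sex = factor(cohort$sex, levels = c("male", "female")))
    if ("marital" %in% names(cohort))
      df$marital <- factor(cohort$marital, levels = .pf_marital_levels)
    if (!is.null(wealth)) df$wealth <- factor(wealth$quintile, levels = 1:5)
    for (d in c("diabetes", "hypertension", "cancer", "tb", "hiv",
                "respiratory", "stroke", "heart"))
      df[[d]] <- clin[[d]]
    df <- df[stats::complete.cases(df), , drop = FALSE]
    # drop terms without variation (e.g. no HIV cases among complete rows)
    for (nm in setdiff(names(df), c(".y", "age")))
      if (length(unique(df[[nm]])) < 2) df[[nm]] <- NULL
    fitg <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
    cf <- summary(fitg)$coefficients
    z <- stats::qnorm(0.975)
    terms <- setdiff(rownames(cf), "(Intercept)")
    tab <- data.frame(term = terms, or = NA_real_, conf_low = NA_real_,
                      conf_high = NA_real_, p = NA_real_, estimable = FALSE,
                      coding = coding, stringsAsFactors = FALSE)
    for (i in seq_along(terms)) {
      b <- cf[terms[i], "Estimate"]; se <- cf[terms[i], "Std. Error"]
      if (!is.finite(b) || abs(b) > 15 || se > 15) next
      tab$or[i] <- exp(b); tab$conf_low[i] <- exp(b - z * se)
      tab$conf_high[i] <- exp(b + z * se)
      tab$p[i] <- cf[terms[i], "Pr(>|z|)"]
      tab$estimable[i] <- TRUE
    }
    out[[length(out) + 1]] <- tab
  }
  do.call(rbind, out)
}

.ewgsop_block <- function(cohort, perf) {
  fl <- ewgsop_flags(perf, cohort$sex)
  out <- list()
  for (s in c("male", "female")) {
    i <- !is.na(cohort$sex) & cohort$sex == s
    for (f in c("low_grip", "low_walk", "very_low_walk", "long_chair")) {
      v <- fl[[f]][i]
      out[[length(out) + 1]] <- cbind(
        data.frame(sex = s, flag = f, stringsAsFactors = FALSE),
        .pct_row(sum(v, na.rm = TRUE), sum(!is.na(v))))
    }
  }
  do.call(rbind, out)
}

#' Write a report bundle to disk
#'
#' Tables as CSV files, plus the whole bundle (with provenance) as JSON.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  pf_assert(inherits(bundle, "report_bundle"), "expected a report_bundle")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("components", "categories", "domains_by_age_sex",
              "adl_by_category", "performance_by_adl", "associations",
              "multivariable", "ewgsop")
  for (t in tables)
    utils::write.csv(bundle[[t]], file.path(dir, paste0(t, ".csv")),
                     row.names = FALSE, na = "")
  utils::write.csv(bundle$baseline$counts,
                   file.path(dir, "baseline_counts.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(bundle$baseline$measures,
                   file.path(dir, "baseline_measures.csv"), row.names = FALSE,
                   na = "")
  payload <- list(provenance = bundle$provenance,
                  categories = bundle$categories,
                  components = bundle$components,
                  ewgsop = bundle$ewgsop)
  jsonlite::write_json(payload, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
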