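# Phenotypic (Fried-type) frailty: covariate-adjusted performance,
# sex-specific quintile cutoffs, five domain flags, 0-5 score and the
# non-frail / prefrail / frail / unable-to-score categories.

#' Sex-specific covariate adjustment model
#'
#' Linear adjustment of a performance measure about a covariate reference
#' value: `adjusted = raw - (covariate - reference) * slope`.  Grip strength
#' is adjusted for body mass index (kg/m^2), walk speed for height (cm), so
#' the quintile cutoffs compare like with like within each sex.
#'
#' @param sex `"male"` or `"female"`.
#' @param measure `"grip"` or `"walk"`.
#' @param slope measure units per covariate unit.
#' @param reference covariate reference value (the stratum mean).
#' @return an `adjustment_model` object.
#' @export
adjustment_model <- function(sex, measure, slope, reference) {
  sex <- match.arg(sex, c("male", "female"))
  measure <- match.arg(measure, c("grip", "walk"))
  pf_assert(is.finite(slope) && is.finite(reference),
            "slope and reference must be finite")
  structure(list(sex = sex, measure = measure,
                 slope = slope, reference = reference),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  covar <- if (x$measure == "grip") "BMI" else "height"
  cat(sprintf("adjusted %s = %s - ((%s - %g) * %g)   [%s]\n",
              x$measure, x$measure, covar, x$reference, x$slope, x$sex))
  invisible(x)
}

#' Published reference adjustment models
#'
#' The fixed adjustment equations derived in a population study of adults
#' aged 40 and over in rural West Africa: grip adjusted for BMI about
#' references 21.6 (men) / 22.4 (women) kg/m^2 with slopes 1.17 / 0.44 kg
#' per unit BMI; walk speed adjusted for height about 172 / 162 cm with
#' slopes 0.00579 / 0.00849 m/s per cm.
#'
#' @return named list of four [adjustment_model()] objects
#'   (`grip.male`, `grip.female`, `walk.male`, `walk.female`).
#' @export
reference_adjustments <- function() {
  list(grip.male = adjustment_model("male", "grip", 1.17, 21.6),
       grip.female = adjustment_model("female", "grip", 0.44, 22.4),
       walk.male = adjustment_model("male", "walk", 0.00579, 172),
       walk.female = adjustment_model("female", "walk", 0.00849, 162))
}

#' Fit a covariate adjustment model from a cohort stratum
#'
#' Ordinary least-squares slope of the aggregated measure on its covariate
#' (grip on BMI, walk speed on height) within one sex stratum; the reference
#' value is the stratum mean covariate rounded to one decimal.
#'
#' @param cohort a `cohort`.
#' @param measure `"grip"` or `"walk"`.
#' @param sex `"male"` or `"female"`.
#' @param perf optional precomputed [summarize_performance()] frame.
#' @return an `adjustment_model`.
#' @export
fit_adjustment <- function(cohort, measure = c("grip", "walk"),
                           sex = c("male", "female"), perf = NULL) {
  measure <- match.arg(measure)
  sex <- match.arg(sex)
  if (is.null(perf)) perf <- summarize_performance(cohort)
  y <- if (measure == "grip") perf$grip_max else perf$walk_speed
  covar_name <- if (measure == "grip") "bmi" else "height"
  pf_assert(covar_name %in% names(cohort), "cohort lacks '%s'", covar_name)
  x <- cohort[[covar_name]]
  keep <- !is.na(cohort$sex) & cohort$sex == sex & !is.na(y) & !is.na(x)
  pf_assert(sum(keep) >= 10,
            "need >= 10 complete (%s, %s) pairs among %ss, have %d",
            measure, covar_name, sex, sum(keep))
  x <- x[keep]; y <- y[keep]
  if (stats::var(x) == 0)
    stop(sprintf("degenerate covariate: %s has zero variance in the %s stratum",
                 covar_name, sex), call. = FALSE)
  slope <- unname(stats::coef(stats::lm(y ~ x))[2])
  adjustment_model(sex, measure, slope, round_half_up(mean(x), 1))
}

#' Apply a covariate adjustment
#'
#' @param raw raw measure values.
#' @param covariate covariate values (BMI for grip, height in cm for walk).
#' @param model an [adjustment_model()].
#' @return adjusted values; missing in, missing out.
#' @export
adjust_measure <- function(raw, covariate, model) {
  pf_assert(inherits(model, "adjustment_model"), "expected an adjustment_model")
  raw - (covariate - model$reference) * model$slope
}

#' Cutoff set for the five frailty domains
#'
#' Per-sex thresholds: adjusted grip and adjusted walk speed flag the lowest
#' quintile (strict `<`), sitting hours flag the highest quintile
#' (non-strict `>=`), weight loss is a fixed >4 kg over the last year, and
#' exhaustion a fixed ordinal frequency level ("3-4 days per week" or more
#' often on either of the two items).
#'
#' @param grip named numeric `c(male=, female=)`, kg (adjusted scale).
#' @param walk named numeric `c(male=, female=)`, m/s (adjusted scale).
#' @param sitting named numeric `c(male=, female=)`, hours/week.
#' @param weight_loss_kg fixed weight-loss threshold, default 4 (positive
#'   iff reported loss strictly exceeds it).
#' @param exhaustion_level ordinal positivity threshold on the 0-3 item
#'   scale, default 2 (= "3-4 days a week").
#' @return a `cutoff_set` object.
#' @export
cutoff_set <- function(grip, walk, sitting, weight_loss_kg = 4,
                       exhaustion_level = 2) {
  for (v in list(grip, walk, sitting))
    pf_assert(all(c("male", "female") %in% names(v)) && all(is.finite(v)),
              "cutoffs must be finite and named male/female")
  structure(list(grip = grip[c("male", "female")],
                 walk = walk[c("male", "female")],
                 sitting = sitting[c("male", "female")],
                 weight_loss_kg = weight_loss_kg,
                 exhaustion_level = exhaustion_level),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("Frailty domain cutoffs (male / female):\n")
  cat(sprintf("  low adjusted grip:   < %.3f / %.3f kg\n", x$grip[1], x$grip[2]))
  cat(sprintf("  low adjusted walk:   < %.3f / %.3f m/s\n", x$walk[1], x$walk[2]))
  cat(sprintf("  low activity:        >= %.1f / %.1f sitting h/wk\n",
              x$sitting[1], x$sitting[2]))
  cat(sprintf("  weight loss:         > %g kg in last year\n", x$weight_loss_kg))
  cat(sprintf("  exhaustion:          either item at level >= %d ('3-4 days/week')\n",
              x$exhaustion_level))
  invisible(x)
}

#' Published reference cutoffs
#'
#' The fixed domain cutoffs from the same West African derivation cohort as
#' [reference_adjustments()]: adjusted grip <37.1 / <25.0 kg, adjusted walk
#' <0.821 / <0.720 m/s, sitting >=34 / >=36 h/week (male / female).
#'
#' @return a [cutoff_set()].
#' @export
reference_cutoffs <- function() {
  cutoff_set(grip = c(male = 37.1, female = 25.0),
             walk = c(male = 0.821, female = 0.720),
             sitting = c(male = 34, female = 36))
}

#' Derive quintile cutoffs from a cohort
#'
#' Computes, within each sex, the 20th percentile of the covariate-adjusted
#' grip and walk distributions and the 80th percentile of sitting hours,
#' among participants with that measure present (denominators therefore
#' differ per component).  Weight-loss and exhaustion thresholds are fixed.
#'
#' @param cohort a `cohort`.
#' @param adjustments list of adjustment models as returned by
#'   [reference_adjustments()] or fitted via [fit_adjustment()]; fitted from
#'   the cohort itself when `NULL`.
#' @param perf optional precomputed performance frame.
#' @param quantile_type quantile rule passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return a `cutoff_set`; the adjustments used are attached as
#'   `attr(, "adjustments")`.
#' @export
derive_cutoffs <- function(cohort, adjustments = NULL, perf = NULL,
                           quantile_type = 7) {
  if (is.null(perf)) perf <- summarize_performance(cohort)
  if (is.null(adjustments))
    adjustments <- list(
      grip.male = fit_adjustment(cohort, "grip", "male", perf),
      grip.female = fit_adjustment(cohort, "grip", "female", perf),
      walk.male = fit_adjustment(cohort, "walk", "male", perf),
      walk.female = fit_adjustment(cohort, "walk", "female", perf))

  adj <- adjusted_measures(cohort, perf, adjustments)
  one <- function(values, sex, probs, label) {
    v <- values[!is.na(cohort$sex) & cohort$sex == sex & !is.na(values)]
    pf_assert(length(v) >= 5,
              "fewer than 5 usable %s values in the %s stratum", label, sex)
    pf_quantile(v, probs, type = quantile_type)
  }
  sitting <- if ("sitting_hours" %in% names(cohort))
    cohort$sitting_hours else rep(NA_real_, nrow(cohort))
  out <- cutoff_set(
    grip = c(male = one(adj$grip_adj, "male", 0.2, "adjusted grip"),
             female = one(adj$grip_adj, "female", 0.2, "adjusted grip")),
    walk = c(male = one(adj$walk_adj, "male", 0.2, "adjusted walk"),
             female = one(adj$walk_adj, "female", 0.2, "adjusted walk")),
    sitting = c(male = one(sitting, "male", 0.8, "sitting hours"),
                female = one(sitting, "female", 0.8, "sitting hours")))
  attr(out, "adjustments") <- adjustments
  out
}

# Adjusted grip and walk for every participant, using the model of their sex.
adjusted_measures <- function(cohort, perf, adjustments) {
  n <- nrow(cohort)
  grip_adj <- walk_adj <- rep(NA_real_, n)
  bmi <- if ("bmi" %in% names(cohort)) cohort$bmi else rep(NA_real_, n)
  height <- if ("height" %in% names(cohort)) cohort$height else rep(NA_real_, n)
  for (s in c("male", "female")) {
    i <- !is.na(cohort$sex) & cohort$sex == s
    grip_adj[i] <- adjust_measure(perf$grip_max[i], bmi[i],
                                  adjustments[[paste0("grip.", s)]])
    walk_adj[i] <- adjust_measure(perf$walk_speed[i], height[i],
                                  adjustments[[paste0("walk.", s)]])
  }
  data.frame(id = cohort$id, grip_adj = grip_adj, walk_adj = walk_adj,
             stringsAsFactors = FALSE)
}

#' Compute the five frailty domain flags
#'
#' Positivity rules, with the strictness of each inequality following the
#' printed cutoff conventions:
#' * weight loss: reported loss strictly greater than 4 kg (integers: >= 5);
#' * exhaustion: either item at or above the "3-4 days a week" level;
#' * low grip: adjusted grip strictly below the sex cutoff;
#' * low walk: adjusted walk speed strictly below the sex cutoff;
#' * low activity: sitting hours at or above the sex cutoff.
#'
#' Any missing underlying datum makes that flag missing; flags are never
#' imputed.
#'
#' @param cohort a `cohort`.
#' @param cutoffs a [cutoff_set()].
#' @param adjustments adjustment-model list (defaults to the models attached
#'   to `cutoffs`, else [reference_adjustments()]).
#' @param perf optional precomputed performance frame.
#' @return data frame of missing-aware logicals `weight_loss`, `exhaustion`,
#'   `low_grip`, `low_walk`, `low_activity`.
#' @export
component_flags <- function(cohort, cutoffs, adjustments = NULL, perf = NULL) {
  pf_assert(inherits(cutoffs, "cutoff_set"), "expected a cutoff_set")
  if (is.null(adjustments))
    adjustments <- attr(cutoffs, "adjustments")
  if (is.null(adjustments)) adjustments <- reference_adjustments()
  if (is.null(perf)) perf <- summarize_performance(cohort)
  n <- nrow(cohort)
  adj <- adjusted_measures(cohort, perf, adjustments)

  col <- function(name) if (name %in% names(cohort)) cohort[[name]]
         else rep(NA_real_, n)
  sexcut <- function(v) unname(v[match(cohort$sex, c("male", "female"))])

  weight_loss <- col("weight_change") > cutoffs$weight_loss_kg
  exh <- pmax(col("exh_effort"), col("exh_get_going"))  # NA if either NA
  exhaustion <- exh >= cutoffs$exhaustion_level
  low_grip <- adj$grip_adj < sexcut(cutoffs$grip)
  low_walk <- adj$walk_adj < sexcut(cutoffs$walk)
  low_activity <- col("sitting_hours") >= sexcut(cutoffs$sitting)

  data.frame(id = cohort$id, weight_loss = weight_loss,
             exhaustion = exhaustion, low_grip = low_grip,
             low_walk = low_walk, low_activity = low_activity,
             stringsAsFactors = FALSE)
}

#' Score the frailty phenotype from domain flags
#'
#' One point per positive domain.  Zero points = non-frail, 1-2 = prefrail,
#' 3 or more = frail.  Under the literal missing-data rule (the default) a
#' participant missing any domain is `unable_to_score` regardless of the
#' observed positives; `strict_missing = FALSE` enables the documented
#' alternative in which 3+ observed positives already label a participant
#' frail even with a missing domain.
#'
#' @param flags data frame with logical columns `weight_loss`, `exhaustion`,
#'   `low_grip`, `low_walk`, `low_activity` (e.g. from [component_flags()]).
#' @param strict_missing logical, see above.
#' @return data frame with `score` (0-5, `NA` when unable) and `category`
#'   (factor: non_frail, prefrail, frail, unable_to_score).
#' @export
score_frailty <- function(flags, strict_missing = TRUE) {
  comp <- c("weight_loss", "exhaustion", "low_grip", "low_walk", "low_activity")
  pf_assert(all(comp %in% names(flags)),
            "flags must contain the five domain columns")
  m <- as.matrix(flags[comp])
  npos <- rowSums(m, na.rm = TRUE)
  nmiss <- rowSums(is.na(m))
  score <- ifelse(nmiss > 0, NA_integer_, as.integer(npos))
  category <- ifelse(nmiss > 0, "unable_to_score",
              ifelse(npos == 0, "non_frail",
              ifelse(npos <= 2, "prefrail", "frail")))
  if (!strict_missing)
    category[nmiss > 0 & npos >= 3] <- "frail"
  out <- data.frame(score = score,
                    category = factor(category,
                      levels = c("non_frail", "prefrail", "frail",
                                 "unable_to_score")),
                    stringsAsFactors = FALSE)
  if ("id" %in% names(flags)) out <- cbind(id = flags$id, out)
  out
}

#' Fit the frailty phenotype to a cohort
#'
#' The central estimator.  In `derive` mode (the default, `cutoffs = NULL`)
#' it fits the sex-specific covariate adjustments by least squares, derives
#' the quintile cutoffs from the cohort, and scores every participant; in
#' fixed mode it applies a supplied [cutoff_set()] (for instance
#' [reference_cutoffs()]) and its adjustment models.  Running derive mode on
#' the cohort that produced a fixed cutoff set reproduces the fixed-mode
#' flags exactly.
#'
#' @param cohort a `cohort`.
#' @param cutoffs `NULL` to derive from the cohort, or a [cutoff_set()].
#' @param adjustments optional adjustment-model list for fixed mode
#'   (defaults to the models attached to `cutoffs`, else
#'   [reference_adjustments()]).
#' @param quantile_type quantile rule for derive mode (default 7).
#' @param strict_missing missing-domain rule, see [score_frailty()].
#' @return an object of class `frailty_fit` with elements `scores` (per
#'   participant: flags, score, category), `cutoffs`, `adjustments`,
#'   `performance`, `mode`, `n` and `call`.  Methods: `print`, `summary`,
#'   `predict`, `coef`, `plot`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 400, seed = 7))
#' fit <- frailty_fit(coh)
#' fit
#' table(fit$scores$category)
#' @export
frailty_fit <- function(cohort, cutoffs = NULL, adjustments = NULL,
                        quantile_type = 7, strict_missing = TRUE) {
  pf_assert(inherits(cohort, "cohort"), "expected a cohort; see as_cohort()")
  pf_assert(nrow(cohort) > 0, "cohort is empty")
  perf <- summarize_performance(cohort)
  mode <- if (is.null(cutoffs)) "derive" else "fixed"
  if (mode == "derive") {
    cutoffs <- derive_cutoffs(cohort, adjustments = adjustments, perf = perf,
                              quantile_type = quantile_type)
    adjustments <- attr(cutoffs, "adjustments")
  } else {
    pf_assert(inherits(cutoffs, "cutoff_set"), "cutoffs must be a cutoff_set")
    if (is.null(adjustments)) adjustments <- attr(cutoffs, "adjustments")
    if (is.null(adjustments)) adjustments <- reference_adjustments()
  }
  flags <- component_flags(cohort, cutoffs, adjustments, perf)
  scores <- cbind(flags,
                  score_frailty(flags, strict_missing)[c("score", "category")])
  structure(list(scores = scores, cutoffs = cutoffs,
                 adjustments = adjustments, performance = perf,
                 mode = mode, strict_missing = strict_missing,
                 quantile_type = quantile_type,
                 n = nrow(cohort), sex = cohort$sex, age = cohort$age,
                 call = match.call()),
            class = "frailty_fit")
}

#' Score a cohort in derive or fixed mode
#'
#' Thin wrapper over [frailty_fit()] using the mode/cutoffs vocabulary of
#' the pipeline interface.
#'
#' @param cohort a `cohort`.
#' @param mode `"derive"` or `"fixed"`.
#' @param cutoffs required [cutoff_set()] when `mode = "fixed"`.
#' @param ... passed to [frailty_fit()].
#' @return a `frailty_fit`.
#' @export
score_cohort <- function(cohort, mode = c("derive", "fixed"), cutoffs = NULL,
                         ...) {
  mode <- match.arg(mode)
  if (mode == "derive") frailty_fit(cohort, cutoffs = NULL, ...)
  else {
    pf_assert(!is.null(cutoffs), "fixed mode requires cutoffs")
    frailty_fit(cohort, cutoffs = cutoffs, ...)
  }
}

#' @export
print.frailty_fit <- function(x, ...) {
  cat(sprintf("Phenotypic frailty fit (%s-mode cutoffs), n = %d\n",
              x$mode, x$n))
  tab <- table(x$scores$category)
  pct <- format_percent(as.numeric(tab), x$n)
  for (i in seq_along(tab))
    cat(sprintf("  %-16s %5d (%.1f%%)\n", names(tab)[i], tab[i], pct[i]))
  invisible(x)
}

#' @export
coef.frailty_fit <- function(object, ...) {
  c(grip_male = unname(object$cutoffs$grip["male"]),
    grip_female = unname(object$cutoffs$grip["female"]),
    walk_male = unname(object$cutoffs$walk["male"]),
    walk_female = unname(object$cutoffs$walk["female"]),
    sitting_male = unname(object$cutoffs$sitting["male"]),
    sitting_female = unname(object$cutoffs$sitting["female"]),
    weight_loss_kg = object$cutoffs$weight_loss_kg,
    exhaustion_level = object$cutoffs$exhaustion_level)
}

#' Summarise a frailty fit
#'
#' Category counts and per-component prevalence with the per-component
#' denominators (participants with that domain observed), mirroring the
#' bookkeeping style of published component tables.
#'
#' @param object a `frailty_fit`.
#' @param ... unused.
#' @return a `summary.frailty_fit` list with `categories` and `components`
#'   data frames.
#' @export
summary.frailty_fit <- function(object, ...) {
  comp <- c("weight_loss", "exhaustion", "low_grip", "low_walk", "low_activity")
  m <- as.matrix(object$scores[comp])
  components <- data.frame(
    component = comp,
    positive = colSums(m, na.rm = TRUE),
    observed = colSums(!is.na(m)),
    missing = colSums(is.na(m)),
    row.names = NULL)
  components$percent <- format_percent(components$positive, components$observed)
  tab <- table(object$scores$category)
  categories <- data.frame(category = names(tab), n = as.numeric(tab),
                           percent = format_percent(as.numeric(tab), object$n))
  structure(list(categories = categories, components = components,
                 cutoffs = object$cutoffs, mode = object$mode, n = object$n),
            class = "summary.frailty_fit")
}

#' @export
print.summary.frailty_fit <- function(x, ...) {
  cat(sprintf("Frailty phenotype summary (n = %d, %s-mode cutoffs)\n\n",
              x$n, x$mode))
  cat("Components (positive/observed, %):\n")
  print(x$components, row.names = FALSE)
  cat("\nCategories:\n")
  print(x$categories, row.names = FALSE)
  cat("\n")
  print(x$cutoffs)
  invisible(x)
}

#' Score new participants with a fitted frailty model
#'
#' Applies the cutoffs and adjustment models stored in the fit to a new
#' cohort (fixed-mode scoring), so cutoffs derived in one cohort can be
#' carried to another.
#'
#' @param object a `frailty_fit`.
#' @param newdata a `cohort`.
#' @param ... unused.
#' @return the `scores` data frame for `newdata`.
#' @export
predict.frailty_fit <- function(object, newdata, ...) {
  pf_assert(inherits(newdata, "cohort"), "newdata must be a cohort")
  flags <- component_flags(newdata, object$cutoffs, object$adjustments)
  cbind(flags, score_frailty(flags, object$strict_missing)[c("score", "category")])
}

#' Plot frailty prevalence by age band and sex
#'
#' @param x a `frailty_fit`.
#' @param include_unable merge unable-to-score with frail (the sensitivity
#'   coding) when `TRUE`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix of percentages plotted.
#' @export
plot.frailty_fit <- function(x, include_unable = FALSE, ...) {
  band <- age_band(x$age)
  frail <- x$scores$category == "frail"
  if (include_unable) frail <- frail | x$scores$category == "unable_to_score"
  tab <- tapply(frail, list(x$sex, band), function(v) 100 * mean(v))
  graphics::barplot(tab, beside = TRUE, legend.text = rownames(tab),
                    ylab = if (include_unable)
                      "% frail or unable to score" else "% frail",
                    xlab = "age band", ...)
  invisible(tab)
}

#' Age bands used throughout the reports
#'
#' @param age numeric ages in years.
#' @return factor with levels 40-49, 50-59, 60-69, 70-79, 80+.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(40, 50, 60, 70, 80, Inf), right = FALSE,
      labels = c("40-49", "50-59", "60-69", "70-79", "80+"))
}

#' Serialize / read a cutoff set as JSON
#'
#' @param cutoffs a [cutoff_set()].
#' @param path output JSON path.
#' @return `path` invisibly (`write_cutoffs`); a `cutoff_set`
#'   (`read_cutoffs`).
#' @export
write_cutoffs <- function(cutoffs, path) {
  pf_assert(inherits(cutoffs, "cutoff_set"), "expected a cutoff_set")
  adj <- attr(cutoffs, "adjustments")
  payload <- unclass(cutoffs)
  for (nm in c("grip", "walk", "sitting"))
    payload[[nm]] <- as.list(payload[[nm]])   # keep names in the JSON object
  if (!is.null(adj))
    payload$adjustments <- lapply(adj, function(m)
      list(sex = m$sex, measure = m$measure, slope = m$slope,
           reference = m$reference))
  # 17 significant digits: cutoffs round-trip bit-exactly, so fixed-mode
  # reuse reproduces derive-mode flags even at tie boundaries
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- cutoff_set(grip = unlist(payload$grip),
                    walk = unlist(payload$walk),
                    sitting = unlist(payload$sitting),
                    weight_loss_kg = payload$weight_loss_kg,
                    exhaustion_level = payload$exhaustion_level)
  if (!is.null(payload$adjustments))
    attr(out, "adjustments") <- lapply(payload$adjustments, function(m)
      adjustment_model(m$sex, m$measure, m$slope, m$reference))
  out
}
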