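# Rule-based disease and ADL-impairment classification.
#
# ADL coding: one ordinal 0-4 scale per item.
#   0 no difficulty, 1 mild, 2 moderate, 3 severe, 4 unable to do.
# The walking item offers no mild/moderate/severe split; "some difficulty"
# is stored as 2.  "Do not want to do" is recorded as NA (missing) for that
# item: the response option is never assigned a severity by the source
# questionnaire, so no impairment level can be attributed to it.
.adl_items <- c(walking = "adl_walking", transfers = "adl_transfers",
                toileting = "adl_toileting", dressing = "adl_dressing",
                bathing = "adl_bathing", eating = "adl_eating")

#' Classify hypertension
#'
#' Hypertension is present given either a self-reported previous diagnosis
#' or treatment, or a mean systolic blood pressure strictly above 140 mmHg,
#' or a mean diastolic strictly above 90 mmHg (means of the second and third
#' readings).  With no self-report and missing blood pressure the status is
#' missing; a single elevated mean suffices even if the other is missing.
#'
#' @param cohort a `cohort`.
#' @param perf optional precomputed [summarize_performance()] frame.
#' @return data frame with logical `hypertension` and a provenance tag
#'   `hypertension_source` in `self_report` / `measured` / `both` (`NA` when
#'   status could not be determined or is negative).
#' @export
classify_hypertension <- function(cohort, perf = NULL) {
  if (is.null(perf)) perf <- summarize_performance(cohort)
  n <- nrow(cohort)
  self <- if ("dx_hypertension" %in% names(cohort))
    cohort$dx_hypertension else rep(NA, n)
  sbp_hi <- perf$sbp_mean > 140
  dbp_hi <- perf$dbp_mean > 90
  measured <- ifelse(isTRUE_v(sbp_hi) | isTRUE_v(dbp_hi), TRUE,
              ifelse(is.na(sbp_hi) | is.na(dbp_hi), NA, FALSE))
  status <- ifelse(isTRUE_v(self), TRUE,
            ifelse(isTRUE_v(measured), TRUE,
            ifelse(is.na(measured), NA, FALSE)))
  source <- rep(NA_character_, n)
  source[isTRUE_v(self) & isTRUE_v(measured)] <- "both"
  source[isTRUE_v(self) & !isTRUE_v(measured)] <- "self_report"
  source[!isTRUE_v(self) & isTRUE_v(measured)] <- "measured"
  data.frame(id = cohort$id, hypertension = status,
             hypertension_source = source, stringsAsFactors = FALSE)
}

# TRUE where x is TRUE, FALSE where FALSE or NA (vectorised isTRUE)
isTRUE_v <- function(x) !is.na(x) & x

#' Classify diabetes mellitus
#'
#' Present given self-reported previous diagnosis or treatment, or a random
#' capillary glucose strictly above 200 mg/dL, or a fasting glucose strictly
#' above 126 mg/dL, or an HbA1c strictly above 6.5%.  When every input is
#' absent the status is missing; a negative requires at least one observed,
#' non-positive input and no positive one.
#'
#' @param cohort a `cohort`.
#' @return data frame with logical `diabetes` and provenance tag
#'   `diabetes_source`.
#' @export
classify_diabetes <- function(cohort) {
  n <- nrow(cohort)
  col <- function(name) if (name %in% names(cohort)) cohort[[name]]
         else rep(NA, n)
  self <- col("dx_diabetes")
  meas <- cbind(col("random_glucose") > 200,
                col("fasting_glucose") > 126,
                col("hba1c") > 6.5)
  any_meas_pos <- apply(meas, 1, function(r) any(isTRUE_v(r)))
  any_observed <- !is.na(self) | apply(meas, 1, function(r) any(!is.na(r)))
  status <- ifelse(isTRUE_v(self) | any_meas_pos, TRUE,
            ifelse(any_observed, FALSE, NA))
  source <- rep(NA_character_, n)
  source[isTRUE_v(self) & any_meas_pos] <- "both"
  source[isTRUE_v(self) & !any_meas_pos] <- "self_report"
  source[!isTRUE_v(self) & any_meas_pos] <- "measured"
  data.frame(id = cohort$id, diabetes = status, diabetes_source = source,
             stringsAsFactors = FALSE)
}

#' Classify ADL impairment
#'
#' Moderate-or-worse difficulty flags an impairment for transfers,
#' toileting, dressing, bathing and eating; for walking, some difficulty or
#' worse already counts ("unable to do" counts as impaired for every item).
#' A "do not want to do" response carries no severity information and is
#' treated as missing for that item.
#'
#' @param cohort a `cohort`.
#' @return data frame with six logical item flags (`adl_walking`, ...) and
#'   `any_adl`, the OR of the six (missing only if no item is observed
#'   impaired and at least one is missing).
#' @export
classify_adl <- function(cohort) {
  n <- nrow(cohort)
  out <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
  for (item in .adl_items) {
    v <- if (item %in% names(cohort)) cohort[[item]] else rep(NA_real_, n)
    threshold <- if (item == "adl_walking") 1 else 2
    out[[item]] <- v >= threshold
  }
  m <- as.matrix(out[.adl_items])
  any_pos <- apply(m, 1, function(r) any(isTRUE_v(r)))
  all_obs <- apply(m, 1, function(r) !anyNA(r))
  out$any_adl <- ifelse(any_pos, TRUE, ifelse(all_obs, FALSE, NA))
  out
}

#' Assemble the clinical profile of a cohort
#'
#' Combines the hypertension and diabetes classifiers, the pass-through
#' self-report disease flags, and the ADL impairment flags into one frame.
#'
#' @param cohort a `cohort`.
#' @param perf optional precomputed performance frame.
#' @return data frame, one row per participant.
#' @export
clinical_profile <- function(cohort, perf = NULL) {
  if (is.null(perf)) perf <- summarize_performance(cohort)
  out <- classify_hypertension(cohort, perf)
  out <- cbind(out, classify_diabetes(cohort)[-1])
  passthrough <- c(cancer = "dx_cancer", tb = "dx_tb", hiv = "dx_hiv",
                   respiratory = "dx_respiratory", stroke = "dx_stroke",
                   heart = "dx_heart")
  for (nm in names(passthrough)) {
    col <- passthrough[[nm]]
    out[[nm]] <- if (col %in% names(cohort)) cohort[[col]]
                 else rep(NA, nrow(cohort))
  }
  cbind(out, classify_adl(cohort)[-1])
}
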