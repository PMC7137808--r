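# Trial aggregation and fixed international (EWGSOP-style) cutoffs.

#' Summarise raw performance trials
#'
#' Aggregates the raw trials of each participant into the analysis
#' measurements:
#' * grip strength = maximum over the available trials (up to two per hand), kg;
#' * walk speed = course length divided by the fastest available time, m/s;
#' * chair-stand time passed through, seconds for five rises;
#' * blood pressure = mean of the second and third readings, missing if
#'   either of those is absent.
#'
#' A measurement with zero usable trials is missing.  The function is fully
#' missing-tolerant; it never imputes.
#'
#' @param cohort a `cohort` object.
#' @param course_m walk course length in metres (default 4, the standard
#'   short-course protocol).
#' @return data frame with columns `id`, `grip_max`, `walk_speed`,
#'   `chair_time`, `sbp_mean`, `dbp_mean`.
#' @export
summarize_performance <- function(cohort, course_m = 4) {
  pf_assert(inherits(cohort, "cohort"), "expected a cohort")
  n <- nrow(cohort)
  getm <- function(cols) {
    cols <- intersect(cols, names(cohort))
    if (!length(cols)) return(matrix(NA_real_, n, 1))
    as.matrix(as.data.frame(cohort)[cols])
  }
  grip <- getm(paste0("grip", 1:4))
  walk <- getm(paste0("walk", 1:2))

  row_stat <- function(m, f) apply(m, 1, function(r)
    if (all(is.na(r))) NA_real_ else f(r, na.rm = TRUE))
  grip_max <- row_stat(grip, max)
  fastest <- row_stat(walk, min)
  walk_speed <- course_m / fastest

  chair <- if ("chair_stand_time" %in% names(cohort))
    cohort$chair_stand_time else rep(NA_real_, n)

  sbp <- getm(paste0("sbp", 2:3))
  dbp <- getm(paste0("dbp", 2:3))
  mean23 <- function(m) ifelse(is.na(m[, 1]) | is.na(m[, 2]), NA_real_,
                               (m[, 1] + m[, 2]) / 2)
  data.frame(id = cohort$id,
             grip_max = grip_max,
             walk_speed = walk_speed,
             chair_time = chair,
             sbp_mean = if (ncol(sbp) == 2) mean23(sbp) else rep(NA_real_, n),
             dbp_mean = if (ncol(dbp) == 2) mean23(dbp) else rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

#' Flag low physical performance against fixed international cutoffs
#'
#' Applies the prespecified sarcopenia-guideline thresholds used for
#' cross-study comparison: low grip strength (<27 kg men, <16 kg women),
#' low walk speed (<0.8 m/s), very low walk speed (<0.6 m/s), and prolonged
#' chair-stand time (>15 s).  All inequalities are strict, exactly as the
#' guideline values are printed; a missing measurement gives a missing flag.
#'
#' @param perf data frame from [summarize_performance()].
#' @param sex character vector (`"male"`/`"female"`), one per row of `perf`.
#' @return data frame of missing-aware logicals `low_grip`, `low_walk`,
#'   `very_low_walk`, `long_chair`.
#' @export
ewgsop_flags <- function(perf, sex) {
  pf_assert(length(sex) == nrow(perf), "sex must match perf rows")
  pf_assert(all(is.na(sex) | sex %in% c("male", "female")),
            "sex must be 'male' or 'female'")
  grip_cut <- ifelse(sex == "male", 27, 16)
  data.frame(id = perf$id,
             low_grip = perf$grip_max < grip_cut,
             low_walk = perf$walk_speed < 0.8,
             very_low_walk = perf$walk_speed < 0.6,
             long_chair = perf$chair_time > 15,
             stringsAsFactors = FALSE)
}
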