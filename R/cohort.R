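# Cohort container: a validated data.frame of one row per participant, with
# explicit missing-data semantics (empty cell on disk, NA in memory; zero is
# never treated as missing).

# Canonical column names.  Asset items are any columns prefixed "asset_".
.pf_numeric_cols <- c(
  "age", "height", "bmi",
  paste0("grip", 1:4), paste0("walk", 1:2),
  "chair_stand_time", "sitting_hours", "weight_change",
  "exh_effort", "exh_get_going",
  "adl_walking", "adl_transfers", "adl_toileting", "adl_dressing",
  "adl_bathing", "adl_eating",
  paste0("sbp", 1:3), paste0("dbp", 1:3),
  "random_glucose", "fasting_glucose", "hba1c"
)
.pf_flag_cols <- c("dx_hypertension", "dx_diabetes", "dx_cancer", "dx_tb",
                   "dx_hiv", "dx_respiratory", "dx_stroke", "dx_heart")
.pf_marital_levels <- c("married_cohabiting", "separated_divorced",
                        "widowed", "never_married")

#' Known cohort columns
#'
#' Names of the canonical participant fields a cohort may carry, excluding
#' the open-ended `asset_*` block.
#' @return character vector of column names.
#' @export
cohort_columns <- function() {
  c("id", "sex", "marital", .pf_numeric_cols, .pf_flag_cols)
}

#' Construct and validate a cohort
#'
#' Coerces a data frame of participant records to a `cohort` object,
#' enforcing the eligibility and measurement invariants: unique ids,
#' age at least 40 years, grip trials in (0, 120] kg, positive walk times
#' and chair-stand times.  Any field other than `id`, `age` and `sex` may be
#' missing (`NA`); missingness is always distinct from zero.
#'
#' @param df data frame with at least columns `id`, `age`, `sex`.
#' @param provenance optional list recording where the cohort came from
#'   (file path, or generator seed and configuration hash).
#' @return a `cohort` object (a data frame).
#' @export
as_cohort <- function(df, provenance = NULL) {
  pf_assert(is.data.frame(df), "as_cohort() expects a data frame")
  for (col in c("id", "age", "sex"))
    pf_assert(col %in% names(df), "mandatory column '%s' is missing", col)
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  df$id <- as.character(df$id)
  pf_assert(!anyNA(df$id) && !any(df$id == ""), "participant ids must be non-missing")
  pf_assert(!anyDuplicated(df$id), "participant ids must be unique")

  sex <- tolower(as.character(df$sex))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  bad <- !is.na(sex) & !sex %in% c("male", "female")
  pf_assert(!any(bad), "unrecognised sex value(s): %s",
            paste(unique(df$sex[bad]), collapse = ", "))
  df$sex <- sex

  if ("marital" %in% names(df)) {
    mar <- as.character(df$marital)
    mar[!is.na(mar) & mar == ""] <- NA
    bad <- !is.na(mar) & !mar %in% .pf_marital_levels
    pf_assert(!any(bad), "unrecognised marital value(s): %s",
              paste(unique(mar[bad]), collapse = ", "))
    df$marital <- mar
  }

  num_cols <- intersect(c(.pf_numeric_cols,
                          grep("^asset_", names(df), value = TRUE)), names(df))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  for (col in intersect(.pf_flag_cols, names(df))) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- rep(NA, length(v))
      parsed[v %in% c("TRUE", "true", "T", "1")] <- TRUE
      parsed[v %in% c("FALSE", "false", "F", "0")] <- FALSE
      v <- parsed
    } else if (is.numeric(v)) v <- v != 0
    df[[col]] <- v
  }

  pf_assert(!anyNA(df$age), "age is mandatory for every participant")
  pf_assert(all(df$age >= 40), "eligibility requires age >= 40; offending id(s): %s",
            paste(utils::head(df$id[df$age < 40], 5), collapse = ", "))

  grip <- as.matrix(df[intersect(paste0("grip", 1:4), names(df))])
  if (length(grip) && any(!is.na(grip) & (grip <= 0 | grip > 120)))
    stop("grip trials must lie in (0, 120] kg; zero is invalid, not missing",
         call. = FALSE)
  walk <- as.matrix(df[intersect(paste0("walk", 1:2), names(df))])
  if (length(walk) && any(!is.na(walk) & walk <= 0))
    stop("walk times must be positive", call. = FALSE)
  if ("chair_stand_time" %in% names(df) &&
      any(!is.na(df$chair_stand_time) & df$chair_stand_time <= 0))
    stop("chair-stand times must be positive", call. = FALSE)

  structure(df, class = c("cohort", "data.frame"),
            provenance = provenance)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d fields\n", nrow(x), ncol(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    cat("  provenance:", paste(names(prov), unlist(lapply(prov, format)),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Reads an RFC-4180 style CSV (UTF-8, header row) into a validated
#' [as_cohort()] object.  Missing values are encoded as empty cells or a
#' configured sentinel.  Datasets whose headers differ from the canonical
#' names can be ingested through a column-mapping dialect.
#'
#' @param path CSV file path.
#' @param dialect optional column mapping: a named character vector
#'   (`canonical_name = "file header"`) or the path of a YAML file holding
#'   one.  Unmapped canonical names are looked up verbatim.
#' @param na character vector of missing-value sentinels (default empty
#'   cell and `"NA"`).
#' @return a `cohort`; the number of cells that failed numeric parsing (and
#'   so became missing) is recorded in `attr(, "parse_failures")`.
#' @export
read_cohort <- function(path, dialect = NULL, na = c("", "NA")) {
  pf_assert(file.exists(path), "no such file: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = na,
                         fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect))
      dialect <- unlist(yaml::read_yaml(dialect))
    pf_assert(is.character(dialect) && !is.null(names(dialect)),
              "dialect must be a named character vector or a YAML file of one")
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      pf_assert(src %in% names(raw),
                "dialect maps '%s' to column '%s', not present in file",
                canon, src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  for (col in c("id", "age", "sex"))
    if (!col %in% names(raw))
      stop(sprintf("mandatory column '%s' not found in %s", col, path),
           call. = FALSE)

  known_num <- intersect(c(.pf_numeric_cols,
                           grep("^asset_", names(raw), value = TRUE)),
                         names(raw))
  failures <- 0L
  for (col in known_num) {
    v <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(parsed)
    if (any(bad)) {
      failures <- failures + sum(bad)
      message(sprintf("read_cohort: %d unparseable value(s) in '%s' set to missing",
                      sum(bad), col))
    }
    raw[[col]] <- parsed
  }
  out <- as_cohort(raw, provenance = list(path = path))
  attr(out, "parse_failures") <- failures
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, so the
#' read/write round trip is the identity on every represented value,
#' including missingness.
#'
#' @param cohort a `cohort` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  pf_assert(inherits(cohort, "cohort"), "write_cohort() expects a cohort")
  df <- as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
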