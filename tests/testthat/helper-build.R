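# Builders for small in-code fixtures.

# A cohort of n participants with every field present and unremarkable
# values; override any column by name.
build_cohort <- function(n = 3, ...) {
  df <- data.frame(
    id = sprintf("T%03d", seq_len(n)),
    age = rep(50, n), sex = rep("male", n),
    marital = rep("married_cohabiting", n),
    height = rep(170, n), bmi = rep(22, n),
    grip1 = rep(40, n), grip2 = rep(40, n),
    grip3 = rep(40, n), grip4 = rep(40, n),
    walk1 = rep(4, n), walk2 = rep(4, n),
    chair_stand_time = rep(12, n), sitting_hours = rep(20, n),
    weight_change = rep(0, n),
    exh_effort = rep(0, n), exh_get_going = rep(0, n),
    adl_walking = rep(0, n), adl_transfers = rep(0, n),
    adl_toileting = rep(0, n), adl_dressing = rep(0, n),
    adl_bathing = rep(0, n), adl_eating = rep(0, n),
    sbp1 = rep(120, n), sbp2 = rep(120, n), sbp3 = rep(120, n),
    dbp1 = rep(80, n), dbp2 = rep(80, n), dbp3 = rep(80, n),
    random_glucose = rep(95, n), fasting_glucose = rep(90, n),
    hba1c = rep(5.5, n),
    dx_hypertension = rep(FALSE, n), dx_diabetes = rep(FALSE, n),
    dx_cancer = rep(FALSE, n), dx_tb = rep(FALSE, n),
    dx_hiv = rep(FALSE, n), dx_respiratory = rep(FALSE, n),
    dx_stroke = rep(FALSE, n), dx_heart = rep(FALSE, n),
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  as_cohort(df)
}

# Generator config with every missingness channel switched off, so every
# participant is fully observed (complete-data study conditions).
complete_config <- function(n, seed, ...) {
  cohort_config(
    n = n, seed = seed,
    missing = c(bmi = 0, height = 0, grip = 0, walk = 0, chair = 0,
                sitting = 0, weight_change = 0, exhaustion = 0, bp = 0,
                adl = 0),
    trial_missing = c(grip = 0, walk = 0),
    marital_missing = 0,
    measured_rates = c(random_glucose = 1, fasting_glucose = 1, hba1c = 1),
    adl = list(refuse_rate = 0),
    ...)
}
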