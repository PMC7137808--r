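# Synthetic cohort generator.
#
# Latent-variable scheme: each participant receives latent grip, walk-speed,
# chair and sitting values built from sex- and age-specific means, covariate
# links (grip-BMI, walk-height), a centred disease "frailty liability", and
# within-person residual noise; observed trials are the latent value plus
# small trial noise, offset so that the aggregated measure (max of four grip
# trials, fastest of two walk times) is unbiased for the latent value.
# Self-reported domains (exhaustion, weight loss) and ADL responses follow
# logistic models on age, sex, liability and standardized performance.

# E[max of k iid N(0,1)] for k = 1..4 (exact to 4 dp); used to offset trial
# noise so the max/fastest aggregate is centred on the latent value.
.e_max_z <- c(0, 0.5642, 0.8463, 1.0294)

#' Generator configuration
#'
#' Builds the configuration of the synthetic cohort generator, starting from
#' defaults calibrated to a published rural West African cohort of adults
#' aged 40+ (its sex-specific measurement moments, age-band composition,
#' disease prevalences, per-component missingness and age gradients of the
#' frailty domains).  Any field can be overridden by name; overrides are
#' validated.
#'
#' @param ... named overrides of the default fields (see the package
#'   vignette for the full catalogue and the calibration rationale).
#' @return a validated `cohort_config` object (a named list).
#' @examples
#' cfg <- cohort_config(n = 500, seed = 42)
#' cfg$p_female
#' @export
cohort_config <- function(...) {
  cfg <- default_config()
  overrides <- list(...)
  for (nm in names(overrides)) {
    pf_assert(nm %in% names(cfg), "unknown config field '%s'", nm)
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      for (sub in names(overrides[[nm]]))
        cfg[[nm]][[sub]] <- overrides[[nm]][[sub]]
    } else cfg[[nm]] <- overrides[[nm]]
  }
  validate_config(cfg)
}

#' Default generator configuration
#'
#' @return the calibrated default `cohort_config`.
#' @export
default_config <- function() {
  cfg <- list(
    n = 2973L,
    seed = 1L,
    # age-band composition (bands 40-49, 50-59, 60-69, 70-79, 80+);
    # ages are drawn uniformly (integer years) within the assigned band
    age_band_weights = c(`40-49` = 1236, `50-59` = 856, `60-69` = 546,
                         `70-79` = 267, `80+` = 68) / 2973,
    age_band_breaks = c(40, 50, 60, 70, 80, 91),
    p_female = 0.506,
    ref_age = 54.4,
    # measurement moments (marginal over the default age mix) and
    # per-decade age-decline slopes back-calculated from the published
    # per-band low-performance prevalences
    grip = list(mean = c(male = 44.9, female = 31.1),
                sd = c(male = 10.4, female = 7.3),
                decline_per_decade = c(male = 5.5, female = 3.0),
                bmi_slope = c(male = 1.17, female = 0.44)),
    walk = list(mean = c(male = 1.04, female = 0.89),
                sd = c(male = 0.27, female = 0.23),
                decline_per_decade = c(male = 0.10, female = 0.09),
                height_slope = c(male = 0.00579, female = 0.00849)),
    bmi = list(mean = c(male = 21.7, female = 22.4),
               sd = c(male = 3.5, female = 4.8)),
    height = list(mean = c(male = 172, female = 162),
                  sd = c(male = 7, female = 6)),
    chair = list(median = c(male = 13, female = 15),
                 sdlog = c(male = 0.268, female = 0.300),
                 rise_log_per_decade = 0.04),
    sitting = list(mean = c(male = 25.6, female = 25.6),
                   sd = c(male = 14.1, female = 14.1),
                   rise_per_decade = 3.0),
    trial_noise = list(grip_kg = 1.0, walk_s = 0.2, n_grip = 4L, n_walk = 2L),
    course_m = 4,
    disease_prev = c(hypertension = 0.367, diabetes = 0.064, cancer = 0.005,
                     tb = 0.018, hiv = 0.005, respiratory = 0.033,
                     stroke = 0.013, heart = 0.055),
    # log-odds-scale liability coefficients linking each disease to the
    # self-reported frailty domains and (scaled) to performance latents;
    # the hypertension value is calibrated so that the full pipeline's
    # age/sex-adjusted frail-vs-rest odds ratio is close to 1.8
    frailty_effects = c(hypertension = 0.52, diabetes = 0.35, cancer = 0,
                        tb = 0.55, hiv = 0, respiratory = 0.10,
                        stroke = 0.35, heart = 0.50),
    performance_effect = 0.30,   # SD shift of grip/walk/sitting per unit liability
    chair_effect = 0.08,         # log-scale shift of chair time per unit liability
    domain_logit = list(
      exhaustion = c(base = -1.59, age = 0.05, female = 0.20, liability = 1.0),
      weight_loss = c(base = -2.35, age = 0.008, female = 0.0, liability = 0.5)),
    exhaustion_item_p = 0.7,     # P(a given item is elevated | component positive)
    adl = list(base = c(walking = -2.19, transfers = -5.09, toileting = -4.85,
                        dressing = -5.62, bathing = -5.04, eating = -5.40),
               perf = 1.2, liability = 0.5, shared = 2.6,
               refuse_rate = 0.002),
    marital_probs = list(
      male = c(married_cohabiting = 0.92, separated_divorced = 0.02,
               widowed = 0.045, never_married = 0.015),
      female = c(married_cohabiting = 0.59, separated_divorced = 0.022,
                 widowed = 0.372, never_married = 0.016)),
    marital_missing = 0.001,
    hypertension_model = list(p_self = 0.40,
                              sbp = c(hyper = 155, normo = 122),
                              sbp_sd = c(hyper = 10, normo = 8),
                              dbp = c(hyper = 92, normo = 76),
                              dbp_sd = c(hyper = 8, normo = 7),
                              reading_sd = 4),
    diabetes_model = list(p_self = 0.35,
                          random_glucose = c(dm = 180, no = 95),
                          random_glucose_sd = c(dm = 40, no = 15),
                          fasting_glucose = c(dm = 140, no = 88),
                          fasting_glucose_sd = c(dm = 30, no = 10),
                          hba1c = c(dm = 7.3, no = 5.5),
                          hba1c_sd = c(dm = 0.8, no = 0.4)),
    assets = list(
      asset_electricity = list(loading = 0.70, cum = 0.85),
      asset_water_source = list(loading = 0.50, cum = c(0.30, 0.70, 0.90)),
      asset_toilet = list(loading = 0.60, cum = c(0.40, 0.80)),
      asset_rooms = list(loading = 0.40, cum = c(0.25, 0.55, 0.80)),
      asset_fuel = list(loading = 0.55, cum = c(0.60, 0.90)),
      asset_livestock = list(loading = 0.35, cum = c(0.30, 0.60, 0.85)),
      asset_land = list(loading = 0.30, cum = c(0.25, 0.60, 0.85)),
      asset_furniture = list(loading = 0.60, cum = c(0.50, 0.85)),
      asset_watch = list(loading = 0.50, cum = 0.70),
      asset_cart = list(loading = 0.45, cum = 0.65),
      asset_phone = list(loading = 0.60, cum = 0.45),
      asset_bank = list(loading = 0.65, cum = 0.90)),
    wealth_age_slope = -0.03,    # latent wealth decline per year over ref
    wealth_liability = -0.30,    # latent wealth per unit frailty liability
    missing = c(bmi = 4, height = 6, grip = 38, walk = 43, chair = 160,
                sitting = 11, weight_change = 103, exhaustion = 1,
                bp = 30, adl = 6) / 2973,
    trial_missing = c(grip = 0.02, walk = 0.02),
    measured_rates = c(random_glucose = 0.5, fasting_glucose = 0.5,
                       hba1c = 0.9))
  class(cfg) <- "cohort_config"
  cfg
}

#' Validate a generator configuration
#'
#' @param cfg a `cohort_config` (or plain list with the same fields).
#' @return the validated config, with age-band weights normalised to sum
#'   exactly to one.
#' @export
validate_config <- function(cfg) {
  pf_assert(is.numeric(cfg$n) && cfg$n >= 1, "n must be >= 1")
  cfg$n <- as.integer(cfg$n)
  pf_assert(is.numeric(cfg$seed) && length(cfg$seed) == 1,
            "seed must be a single integer")
  w <- cfg$age_band_weights
  pf_assert(length(w) == 5 && all(w >= 0) && sum(w) > 0,
            "age_band_weights must be 5 non-negative proportions")
  pf_assert(abs(sum(w) - 1) < 0.01, "age_band_weights must sum to 1")
  cfg$age_band_weights <- w / sum(w)
  pf_assert(cfg$p_female >= 0 && cfg$p_female <= 1, "p_female must be in [0,1]")
  for (blk in c("grip", "walk", "bmi", "height"))
    pf_assert(all(cfg[[blk]]$sd > 0), "%s SDs must be positive", blk)
  pf_assert(all(cfg$chair$sdlog > 0) && all(cfg$sitting$sd > 0),
            "chair/sitting spreads must be positive")
  pf_assert(all(cfg$disease_prev >= 0 & cfg$disease_prev <= 1),
            "disease prevalences must be in [0,1]")
  pf_assert(all(names(cfg$frailty_effects) %in% names(cfg$disease_prev)),
            "frailty_effects must be named after diseases")
  pf_assert(all(cfg$missing >= 0 & cfg$missing < 1),
            "missingness rates must be in [0,1)")
  # residual within-age SDs must remain positive once age and covariate
  # variance components are removed from the marginal SD targets
  va <- .age_variance(cfg)
  for (s in c("male", "female")) {
    gs <- .resid_sd(cfg$grip$sd[s], cfg$grip$decline_per_decade[s] / 10, va,
                    cfg$grip$bmi_slope[s] * cfg$bmi$sd[s])
    ws <- .resid_sd(cfg$walk$sd[s], cfg$walk$decline_per_decade[s] / 10, va,
                    cfg$walk$height_slope[s] * cfg$height$sd[s])
    ss <- .resid_sd(cfg$sitting$sd[s], cfg$sitting$rise_per_decade / 10, va, 0)
    pf_assert(all(is.finite(c(gs, ws, ss))),
              "decline slopes are inconsistent with the marginal SDs (%s)", s)
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n = %d, seed = %d, p_female = %.3f\n",
              x$n, as.integer(x$seed), x$p_female))
  cat("  age bands:", paste(sprintf("%s %.1f%%", names(x$age_band_weights),
                                    100 * x$age_band_weights), collapse = ", "), "\n")
  invisible(x)
}

# variance of age under the band mixture with uniform-integer ages in bands
.age_variance <- function(cfg) {
  br <- cfg$age_band_breaks
  w <- cfg$age_band_weights
  mid <- v <- numeric(length(w))
  for (b in seq_along(w)) {
    ages <- br[b]:(br[b + 1] - 1)
    mid[b] <- mean(ages); v[b] <- stats::var(ages) * (length(ages) - 1) / length(ages)
  }
  m <- sum(w * mid)
  list(mean = m, var = sum(w * (v + mid^2)) - m^2)
}

.resid_sd <- function(marginal_sd, slope_per_year, age_var, covar_sd_contrib) {
  v <- marginal_sd^2 - slope_per_year^2 * age_var$var - covar_sd_contrib^2
  if (v <= 0) return(NaN)
  sqrt(v)
}

# truncated-at-lower normal via resampling (no point mass at the bound)
rtnorm <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:100) {
    bad <- x <= lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
  }
  pmax(x, lower + 1e-6)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of `config$n` participants with the statistical structure
#' the scoring pipeline assumes: truncated-normal grip/walk/BMI per sex with
#' linear age decline and covariate links, log-normal chair-stand times,
#' logistic self-report domains driven by age, sex and a centred
#' disease-liability term, ADL responses correlated with standardized
#' performance, raw trials around each latent value (four grip trials, two
#' walk times, three blood-pressure readings), ordinal asset items from a
#' single latent wealth factor, and per-measurement missingness.
#' Reproducible: the same config (including its seed) yields the identical
#' cohort; the caller's RNG state is untouched.
#'
#' @param config a [cohort_config()].
#' @return a `cohort` with provenance `list(seed, config_hash)`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 200, seed = 3))
#' nrow(coh)
#' @export
generate_cohort <- function(config = default_config()) {
  config <- validate_config(config)
  with_preserved_seed(as.integer(config$seed), .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n
  va <- .age_variance(cfg)

  band <- sample(seq_along(cfg$age_band_weights), n, replace = TRUE,
                 prob = cfg$age_band_weights)
  br <- cfg$age_band_breaks
  age <- br[band] + floor(stats::runif(n) * (br[band + 1] - br[band]))
  sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
  fem <- sex == "female"
  sx <- function(v) unname(v[ifelse(fem, "female", "male")])
  dage <- age - cfg$ref_age

  # diseases and centred frailty liability
  dz <- matrix(stats::runif(n * length(cfg$disease_prev)) <
                 rep(cfg$disease_prev, each = n),
               nrow = n, dimnames = list(NULL, names(cfg$disease_prev)))
  eff <- cfg$frailty_effects[colnames(dz)]
  eff[is.na(eff)] <- 0
  liab <- drop(dz %*% eff) - sum(eff * cfg$disease_prev[colnames(dz)])

  # anthropometry
  bmi <- rtnorm(n, sx(cfg$bmi$mean), sx(cfg$bmi$sd), lower = 10)
  height <- rtnorm(n, sx(cfg$height$mean), sx(cfg$height$sd), lower = 120)

  # latent performance
  grip_resid_sd <- ifelse(fem,
    .resid_sd(cfg$grip$sd["female"], cfg$grip$decline_per_decade["female"] / 10,
              va, cfg$grip$bmi_slope["female"] * cfg$bmi$sd["female"]),
    .resid_sd(cfg$grip$sd["male"], cfg$grip$decline_per_decade["male"] / 10,
              va, cfg$grip$bmi_slope["male"] * cfg$bmi$sd["male"]))
  walk_resid_sd <- ifelse(fem,
    .resid_sd(cfg$walk$sd["female"], cfg$walk$decline_per_decade["female"] / 10,
              va, cfg$walk$height_slope["female"] * cfg$height$sd["female"]),
    .resid_sd(cfg$walk$sd["male"], cfg$walk$decline_per_decade["male"] / 10,
              va, cfg$walk$height_slope["male"] * cfg$height$sd["male"]))

  grip_lat <- sx(cfg$grip$mean) - sx(cfg$grip$decline_per_decade) / 10 * dage +
    sx(cfg$grip$bmi_slope) * (bmi - sx(cfg$bmi$mean)) -
    cfg$performance_effect * grip_resid_sd * liab +
    stats::rnorm(n, 0, grip_resid_sd)
  grip_lat <- pmax(grip_lat, 2)
  walk_lat <- sx(cfg$walk$mean) - sx(cfg$walk$decline_per_decade) / 10 * dage +
    sx(cfg$walk$height_slope) * (height - sx(cfg$height$mean)) -
    cfg$performance_effect * walk_resid_sd * liab +
    stats::rnorm(n, 0, walk_resid_sd)
  walk_lat <- pmax(walk_lat, 0.05)

  # observed trials, offset so max/fastest is centred on the latent value
  kg <- cfg$trial_noise$n_grip
  gsd <- cfg$trial_noise$grip_kg
  grip_trials <- matrix(grip_lat - .e_max_z[kg] * gsd, n, kg) +
    matrix(stats::rnorm(n * kg, 0, gsd), n, kg)
  grip_trials[] <- pmin(pmax(grip_trials, 0.5), 120)

  kw <- cfg$trial_noise$n_walk
  wsd <- cfg$trial_noise$walk_s
  t_base <- cfg$course_m / walk_lat
  walk_times <- matrix(t_base + .e_max_z[kw] * wsd, n, kw) +
    matrix(stats::rnorm(n * kw, 0, wsd), n, kw)
  walk_times[] <- pmax(walk_times, 0.5)

  chair <- exp(log(sx(cfg$chair$median)) +
                 cfg$chair$rise_log_per_decade / 10 * dage +
                 cfg$chair_effect * liab +
                 stats::rnorm(n, 0, sx(cfg$chair$sdlog)))

  sit_resid_sd <- ifelse(fem,
    .resid_sd(cfg$sitting$sd["female"], cfg$sitting$rise_per_decade / 10, va, 0),
    .resid_sd(cfg$sitting$sd["male"], cfg$sitting$rise_per_decade / 10, va, 0))
  # one-step correction so the zero-truncated mean stays on target
  sit_mu <- sx(cfg$sitting$mean) + cfg$sitting$rise_per_decade / 10 * dage +
    cfg$performance_effect * sit_resid_sd * liab
  alpha <- sit_mu / sit_resid_sd
  sit_mu <- sit_mu - sit_resid_sd * stats::dnorm(alpha) / stats::pnorm(alpha)
  sitting <- rtnorm(n, sit_mu, sit_resid_sd, lower = 0)

  # standardized performance deficit for the ADL model (marginal per sex,
  # so it carries both the age signal and individual residuals)
  z_grip <- (grip_lat - sx(cfg$grip$mean)) / sx(cfg$grip$sd)
  z_walk <- (walk_lat - sx(cfg$walk$mean)) / sx(cfg$walk$sd)
  deficit <- -(z_grip + z_walk) / 2

  # self-reported domains
  dl <- cfg$domain_logit
  p_exh <- stats::plogis(dl$exhaustion["base"] + dl$exhaustion["age"] * dage +
                           dl$exhaustion["female"] * fem +
                           dl$exhaustion["liability"] * liab)
  exh_pos <- stats::runif(n) < p_exh
  pe <- cfg$exhaustion_item_p
  elev1 <- exh_pos & (stats::runif(n) < pe)
  elev2 <- exh_pos & (stats::runif(n) < pe)
  force1 <- exh_pos & !elev1 & !elev2    # "either item" rule needs >= 1 elevated
  elev1 <- elev1 | force1
  lvl <- function(elev) ifelse(elev,
                               ifelse(stats::runif(n) < 0.7, 2, 3),
                               ifelse(stats::runif(n) < 0.7, 0, 1))
  exh_effort <- lvl(elev1)
  exh_get_going <- lvl(elev2)

  p_wl <- stats::plogis(dl$weight_loss["base"] + dl$weight_loss["age"] * dage +
                          dl$weight_loss["female"] * fem +
                          dl$weight_loss["liability"] * liab)
  wl_pos <- stats::runif(n) < p_wl
  weight_change <- ifelse(wl_pos, 5L + stats::rpois(n, 2),
                          pmin(pmax(round(stats::rnorm(n, 0, 2.2)), -6L), 4L))

  # ADL items: a shared person-level disability factor makes impairments
  # co-occur (the observed any-ADL rate is only a little above the walking
  # rate), on top of the performance and liability links
  adl_u <- stats::rnorm(n)
  adl <- matrix(NA_real_, n, length(.adl_items),
                dimnames = list(NULL, .adl_items))
  for (item in names(cfg$adl$base)) {
    p_imp <- stats::plogis(cfg$adl$base[item] + cfg$adl$perf * deficit +
                             cfg$adl$liability * liab +
                             cfg$adl$shared * adl_u)
    imp <- stats::runif(n) < p_imp
    colname <- paste0("adl_", item)
    if (item == "walking") {
      adl[, colname] <- ifelse(imp, ifelse(stats::runif(n) < 0.9, 2, 4), 0)
    } else {
      u <- stats::runif(n)
      adl[, colname] <- ifelse(imp, ifelse(u < 0.6, 2, ifelse(u < 0.9, 3, 4)),
                               ifelse(stats::runif(n) < 0.8, 0, 1))
    }
  }

  # blood pressure (three readings around a person-level mean)
  hm <- cfg$hypertension_model
  hyper <- dz[, "hypertension"]
  sbp_mu <- ifelse(hyper, hm$sbp["hyper"], hm$sbp["normo"]) +
    stats::rnorm(n, 0, ifelse(hyper, hm$sbp_sd["hyper"], hm$sbp_sd["normo"]))
  dbp_mu <- ifelse(hyper, hm$dbp["hyper"], hm$dbp["normo"]) +
    stats::rnorm(n, 0, ifelse(hyper, hm$dbp_sd["hyper"], hm$dbp_sd["normo"]))
  reading <- function(mu) round(mu + stats::rnorm(n, 0, hm$reading_sd), 0)
  sbp <- matrix(c(reading(sbp_mu), reading(sbp_mu), reading(sbp_mu)), ncol = 3)
  dbp <- matrix(c(reading(dbp_mu), reading(dbp_mu), reading(dbp_mu)), ncol = 3)
  self_hyper <- hyper & stats::runif(n) < hm$p_self

  dmm <- cfg$diabetes_model
  dm <- dz[, "diabetes"]
  pick <- function(par, sdpar) stats::rnorm(n, ifelse(dm, par["dm"], par["no"]),
                                            ifelse(dm, sdpar["dm"], sdpar["no"]))
  random_glucose <- pmax(pick(dmm$random_glucose, dmm$random_glucose_sd), 40)
  fasting_glucose <- pmax(pick(dmm$fasting_glucose, dmm$fasting_glucose_sd), 40)
  hba1c <- pmax(pick(dmm$hba1c, dmm$hba1c_sd), 3.5)
  self_dm <- dm & stats::runif(n) < dmm$p_self

  # marital status
  marital <- character(n)
  for (s in c("male", "female")) {
    i <- which(sex == s)
    marital[i] <- sample(names(cfg$marital_probs[[s]]), length(i),
                         replace = TRUE, prob = cfg$marital_probs[[s]])
  }
  marital[stats::runif(n) < cfg$marital_missing] <- NA

  # assets from a single latent wealth factor
  wnorm <- sqrt(1 + cfg$wealth_age_slope^2 * va$var +
                  cfg$wealth_liability^2 * stats::var(liab))
  wealth <- (stats::rnorm(n) + cfg$wealth_age_slope * dage +
               cfg$wealth_liability * liab) / wnorm
  assets <- lapply(cfg$assets, function(it) {
    ystar <- it$loading * wealth +
      sqrt(1 - it$loading^2) * stats::rnorm(n)
    findInterval(ystar, stats::qnorm(it$cum)) + 1L
  })

  df <- data.frame(id = sprintf("P%05d", seq_len(n)), age = age, sex = sex,
                   marital = marital, height = height, bmi = bmi,
                   stringsAsFactors = FALSE)
  for (j in seq_len(kg)) df[[paste0("grip", j)]] <- grip_trials[, j]
  for (j in seq_len(kw)) df[[paste0("walk", j)]] <- walk_times[, j]
  df$chair_stand_time <- chair
  df$sitting_hours <- sitting
  df$weight_change <- weight_change
  df$exh_effort <- exh_effort
  df$exh_get_going <- exh_get_going
  for (col in colnames(adl)) df[[col]] <- adl[, col]
  for (j in 1:3) df[[paste0("sbp", j)]] <- sbp[, j]
  for (j in 1:3) df[[paste0("dbp", j)]] <- dbp[, j]
  df$random_glucose <- random_glucose
  df$fasting_glucose <- fasting_glucose
  df$hba1c <- hba1c
  df$dx_hypertension <- self_hyper
  df$dx_diabetes <- self_dm
  df$dx_cancer <- dz[, "cancer"]
  df$dx_tb <- dz[, "tb"]
  df$dx_hiv <- dz[, "hiv"]
  df$dx_respiratory <- dz[, "respiratory"]
  df$dx_stroke <- dz[, "stroke"]
  df$dx_heart <- dz[, "heart"]
  for (nm in names(assets)) df[[nm]] <- assets[[nm]]

  df <- .apply_missingness(df, cfg)
  as_cohort(df, provenance = list(
    seed = as.integer(cfg$seed),
    config_hash = config_hash(cfg)))
}

# per-measurement missingness (applied independently of everything else)
.apply_missingness <- function(df, cfg) {
  n <- nrow(df)
  mr <- cfg$missing
  drop <- function(cols, rate) {
    hit <- stats::runif(n) < rate
    for (col in cols) df[[col]][hit] <<- NA
  }
  drop("bmi", mr["bmi"]); drop("height", mr["height"])
  drop(paste0("grip", seq_len(cfg$trial_noise$n_grip)), mr["grip"])
  drop(paste0("walk", seq_len(cfg$trial_noise$n_walk)), mr["walk"])
  drop("chair_stand_time", mr["chair"])
  drop("sitting_hours", mr["sitting"])
  drop("weight_change", mr["weight_change"])
  drop(c("exh_effort", "exh_get_going"), mr["exhaustion"])
  drop(c(paste0("sbp", 1:3), paste0("dbp", 1:3)), mr["bp"])
  for (col in .adl_items) {
    hit <- stats::runif(n) < (mr["adl"] + cfg$adl$refuse_rate)
    df[[col]][hit] <- NA
  }
  # additional single-trial dropout so aggregation over partial trials
  # is exercised
  for (j in seq_len(cfg$trial_noise$n_grip)) {
    hit <- stats::runif(n) < cfg$trial_missing["grip"]
    df[[paste0("grip", j)]][hit] <- NA
  }
  for (j in seq_len(cfg$trial_noise$n_walk)) {
    hit <- stats::runif(n) < cfg$trial_missing["walk"]
    df[[paste0("walk", j)]][hit] <- NA
  }
  for (g in names(cfg$measured_rates)) {
    hit <- stats::runif(n) >= cfg$measured_rates[g]
    df[[g]][hit] <- NA
  }
  df
}

#' Hash of a generator configuration (for provenance records)
#'
#' @param cfg a `cohort_config`.
#' @return short character hash.
#' @export
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 10)),
             collapse = "\n")
  # djb2 rolling hash; provenance only, not cryptographic
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Read a generator configuration from a YAML/JSON file
#'
#' Plain key-value overrides are merged into [default_config()] and
#' validated.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return a `cohort_config`.
#' @export
read_config <- function(path) {
  pf_assert(file.exists(path), "no such file: %s", path)
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
  names(overrides)[names(overrides) %in% c("FALSE", "F")] <- "n"
  do.call(cohort_config, overrides)
}
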