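#' Direct hourly emission of spectral-input feature series
#'
#' Fast generator tier: emits the hourly location-variance and entropy series
#' of one participant directly from the latent mobility-scale process,
#' bypassing GPS emission and preprocessing. Bipolar participants carry
#' sinusoidal amplitude modulation at `bp_periods`; major-depression
#' participants carry a spectrally flat (aperiodic) fluctuation of matched
#' scale; controls only the observation noise. Used for the spectral and
#' group-separation property studies, where thousands of participant-windows
#' are needed.
#'
#' @param group `"HC"`, `"BP"`, or `"MDD"`.
#' @param n_days window length in days (default 28).
#' @param bp_periods,bp_amplitude,mdd_amplitude,noise_sd dynamics parameters,
#'   as in [cohort_config()].
#' @param lv_base,entropy_base feature baselines (log m^2 and nats).
#' @param seed RNG seed.
#' @return data.frame `t_days` (hourly grid), `lv`, `entropy`.
#' @export
simulate_feature_hours <- function(group, n_days = 28, bp_periods = c(1, 4, 9),
                                   bp_amplitude = 1, mdd_amplitude = 0.5,
                                   noise_sd = 0.5, lv_base = 10,
                                   entropy_base = 1.5, seed = 1) {
  set.seed(seed)
  t_days <- (seq_len(n_days * 24) - 1) / 24
  n <- length(t_days)
  mod <- numeric(n)
  if (group == "BP") {
    phases <- runif(length(bp_periods), 0, 2 * pi)
    for (j in seq_along(bp_periods))
      mod <- mod + bp_amplitude * sin(2 * pi * t_days / bp_periods[j] + phases[j])
  } else if (group == "MDD") {
    mod <- rnorm(n, 0, mdd_amplitude)
  }
  data.frame(t_days = t_days,
             lv = lv_base + mod + rnorm(n, 0, noise_sd),
             entropy = pmax(0, entropy_base + 0.3 * mod + rnorm(n, 0, 0.3 * noise_sd)))
}

#' Direct person-day emission of mobility features and mood flags
#'
#' Fast generator tier for the day-level logistic analyses: draws participant
#' covariates, a depressed/non-depressed flag per day (probability modulated
#' by the covariates), and the eight mobility features with stratum-specific
#' depressed-day shifts - negative weekday shifts on location variance and
#' transition time, and a negative weekend shift on entropy, mirroring the
#' coupling the full trajectory generator produces by construction. Setting
#' every `*_effect` to 0 gives the null generator.
#'
#' @param n_participants,n_days cohort size and follow-up length.
#' @param dep_rate baseline probability that a day is depressed.
#' @param weekday_lv_effect,weekday_tt_effect additive shifts of LV (log m^2)
#'   and TT (fraction) on depressed weekdays.
#' @param weekend_entropy_effect additive entropy shift (nats) on depressed
#'   weekend days.
#' @param covariate_effects logit-scale effects of male sex, age (per year,
#'   centered at 41), and employment on the depressed-day probability.
#' @param start_date date of day 1 (sets the weekday pattern).
#' @param seed RNG seed.
#' @return a person-day data.frame: `participant_id`, `date`, `weekday`,
#'   features `lv`, `sm`, `sv`, `nc`, `entropy`, `homestay`, `tt`, `td`,
#'   flags `depressed`, `manic`, `fatigued`, `irritable`, covariates `age`,
#'   `sex`, `employee_or_student`, `antidepressant`, `group`.
#' @export
simulate_person_days <- function(n_participants = 62, n_days = 84,
                                 dep_rate = 0.35,
                                 weekday_lv_effect = -1.2,
                                 weekday_tt_effect = -0.10,
                                 weekend_entropy_effect = -0.5,
                                 covariate_effects = c(sex = -0.3, age = -0.01,
                                                       employment = -0.2),
                                 start_date = as.Date("2020-01-01"), seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    age <- round(min(75, max(20, rnorm(1, 41, 12))))
    sex <- sample(c("F", "M"), 1, prob = c(0.63, 0.37))
    emp <- rbinom(1, 1, 0.7)
    antidep <- rbinom(1, 1, 0.7)
    group <- sample(c("BP", "MDD"), 1, prob = c(20, 27))
    date <- start_date + seq_len(n_days) - 1
    wd <- as.POSIXlt(date)$wday
    weekday <- wd >= 1 & wd <= 5
    lp <- stats::qlogis(dep_rate) + covariate_effects[["sex"]] * (sex == "M") +
      covariate_effects[["age"]] * (age - 41) + covariate_effects[["employment"]] * emp
    dep <- rbinom(n_days, 1, stats::plogis(lp)) == 1
    d_wd <- dep & weekday
    d_we <- dep & !weekday
    lv <- rnorm(n_days, 10, 2) + weekday_lv_effect * d_wd
    tt <- pmin(0.95, pmax(0.005, rnorm(n_days, 0.20, 0.10) + weekday_tt_effect * d_wd))
    entropy <- pmax(0, rnorm(n_days, 1.3, 0.5) + weekend_entropy_effect * d_we)
    rows[[i]] <- data.frame(
      participant_id = sprintf("P%02d", i), date = date, weekday = weekday,
      lv = lv, sm = pmax(0, rnorm(n_days, 0.35, 0.15)),
      sv = pmax(0, rnorm(n_days, 0.5, 0.25)),
      nc = 1 + rpois(n_days, 3), entropy = entropy,
      homestay = pmin(1, pmax(0, rnorm(n_days, 0.6, 0.2))), tt = tt,
      td = rlnorm(n_days, log(8000), 0.6),
      depressed = dep, manic = rbinom(n_days, 1, 0.15) == 1,
      fatigued = rbinom(n_days, 1, 0.3) == 1,
      irritable = rbinom(n_days, 1, 0.25) == 1,
      age = age, sex = sex, employee_or_student = emp,
      antidepressant = antidep, group = group, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coupled daily mood / mobility series (timescale study)
#'
#' Emits one daily mobility feature and one continuous daily mood score whose
#' coupling lives entirely in the day-to-day fluctuations: each shares the
#' white component `u_t`, while each also carries an independent slow
#' seasonal drift. Aggregating to coarser windows averages the shared
#' component away, so daily correlations exceed monthly ones - the behaviour
#' the timescale analysis probes.
#'
#' @param n_participants,n_days cohort size and follow-up length.
#' @param coupling loading of the shared daily component on the feature.
#' @param drift_amplitude amplitude of the independent seasonal drifts.
#' @param noise_sd feature-specific daily noise sd.
#' @param seed RNG seed.
#' @return data.frame `participant_id`, `day`, `ema` (continuous score),
#'   `lv`.
#' @export
simulate_coupled_series <- function(n_participants = 12, n_days = 180,
                                    coupling = 0.6, drift_amplitude = 1,
                                    noise_sd = 1, seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    day <- seq_len(n_days)
    u <- rnorm(n_days)
    drift_m <- drift_amplitude * sin(2 * pi * day / 90 + runif(1, 0, 2 * pi))
    drift_f <- drift_amplitude * sin(2 * pi * day / 90 + runif(1, 0, 2 * pi))
    rows[[i]] <- data.frame(
      participant_id = sprintf("P%02d", i), day = day,
      ema = 2.5 + 0.8 * u + 0.5 * drift_m + rnorm(n_days, 0, 0.5),
      lv = 10 + rnorm(1, 0, 1) - coupling * u + drift_f + rnorm(n_days, 0, noise_sd))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
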