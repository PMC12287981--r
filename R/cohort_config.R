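#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulated study: group sizes, follow-up length,
#' the GPS duty cycle, measurement noise, missingness, the mood-to-mobility
#' coupling, and the group-specific mood/mobility dynamics (bipolar
#' participants carry amplitude cycles at `bp_periods`; major-depression
#' participants carry an aperiodic, spectrally flat fluctuation; controls are
#' quiet). Defaults emulate the study design the package analyses: a 62-person
#' cohort (15 HC / 20 BP / 27 MDD) followed for 6 months with a 60 s on / 600 s
#' off GPS duty cycle sampled at 1 Hz.
#'
#' @param n_hc,n_bp,n_mdd participants per group (healthy control, bipolar,
#'   major depressive disorder).
#' @param n_days follow-up length in days.
#' @param on_s,off_s duty-cycle on/off durations in seconds.
#' @param rate_hz sampling rate during the on-cycle (Hz).
#' @param gps_noise_sd isotropic GPS noise standard deviation (m).
#' @param accuracy_tail_prob fraction of fixes whose reported accuracy exceeds
#'   50 m (so the accuracy filter is exercised).
#' @param missing_day_prob,missing_hour_prob probability that a whole day /
#'   a given hour of GPS data is lost.
#' @param mood_effect named length-3 vector of per-unit-mood multiplicative
#'   reductions applied to the mobility `scale` (number of excursions),
#'   `transition` (away-time fraction) and `diversity` (novel-place
#'   probability). One EMA depression point above 1 multiplies each target by
#'   `(1 - effect)`.
#' @param bp_periods cycle lengths (days) of the bipolar amplitude modulation;
#'   must lie in `(0, n_days/2]`.
#' @param bp_amplitude,mdd_amplitude latent oscillation amplitudes: sinusoidal
#'   for BP, spectrally flat (aperiodic) for MDD.
#' @param noise_sd day-to-day latent mood noise sd (patients).
#' @param hc_mood_sd latent mood sd in controls.
#' @param hc_dep_rate,patient_dep_rate,bp_mania_rate target fractions of days
#'   with the EMA item above 1; the EMA cut-points are placed so the realized
#'   rates match these in expectation.
#' @param rate_dispersion sd of a per-participant logit-scale shift of the
#'   mood-day rates (heterogeneity knob; 0 = homogeneous).
#' @param ema_miss_primary probability the 12:45 prompt is missed (the 17:00
#'   fallback is used); `ema_miss_both` probability both prompts are missed.
#' @param ema_miss_both see `ema_miss_primary`.
#' @param cluster_radius_m radius of the greedy location clusterer (m).
#' @param tz_offset_h fixed local timezone offset (hours east of UTC).
#' @param start_date local calendar date of follow-up day 1.
#' @param seed integer root seed.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_hc = 15, n_bp = 20, n_mdd = 27, n_days = 180,
                          on_s = 60, off_s = 600, rate_hz = 1,
                          gps_noise_sd = 3, accuracy_tail_prob = 0.05,
                          missing_day_prob = 0.05, missing_hour_prob = 0.05,
                          mood_effect = c(scale = 0.25, transition = 0.25, diversity = 0.2),
                          bp_periods = c(1, 4, 9),
                          bp_amplitude = 1, mdd_amplitude = 0.5,
                          noise_sd = 0.5, hc_mood_sd = 0.5,
                          hc_dep_rate = 0.09, patient_dep_rate = 0.44,
                          bp_mania_rate = 0.48, rate_dispersion = 0,
                          ema_miss_primary = 0.15, ema_miss_both = 0.05,
                          cluster_radius_m = 500, tz_offset_h = 8,
                          start_date = as.Date("2020-01-01"), seed = 1L) {
  check_count(n_hc, "n_hc"); check_count(n_bp, "n_bp"); check_count(n_mdd, "n_mdd")
  check_count(n_days, "n_days")
  check_pos(on_s, "on_s"); check_pos(off_s, "off_s", strict = FALSE)
  check_pos(rate_hz, "rate_hz")
  check_pos(gps_noise_sd, "gps_noise_sd", strict = FALSE)
  for (p in c("accuracy_tail_prob", "missing_day_prob", "missing_hour_prob",
              "hc_dep_rate", "patient_dep_rate", "bp_mania_rate",
              "ema_miss_primary", "ema_miss_both"))
    check_prob(get(p), p)
  if (length(mood_effect) != 3 || any(mood_effect < 0) || any(mood_effect >= 1))
    stopf("'mood_effect' must be 3 reduction fractions in [0, 1)")
  names(mood_effect) <- c("scale", "transition", "diversity")
  if (length(bp_periods) < 1 || any(bp_periods <= 0) || any(bp_periods > n_days / 2))
    stopf("'bp_periods' must lie in (0, n_days/2]")
  check_pos(bp_amplitude, "bp_amplitude", strict = FALSE)
  check_pos(mdd_amplitude, "mdd_amplitude", strict = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  check_pos(hc_mood_sd, "hc_mood_sd")
  check_pos(rate_dispersion, "rate_dispersion", strict = FALSE)
  check_pos(cluster_radius_m, "cluster_radius_m")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stopf("'seed' must be an integer scalar")
  cfg <- list(
    n_hc = as.integer(n_hc), n_bp = as.integer(n_bp), n_mdd = as.integer(n_mdd),
    n_days = as.integer(n_days), on_s = on_s, off_s = off_s, rate_hz = rate_hz,
    gps_noise_sd = gps_noise_sd, accuracy_tail_prob = accuracy_tail_prob,
    missing_day_prob = missing_day_prob, missing_hour_prob = missing_hour_prob,
    mood_effect = mood_effect, bp_periods = bp_periods,
    bp_amplitude = bp_amplitude, mdd_amplitude = mdd_amplitude,
    noise_sd = noise_sd, hc_mood_sd = hc_mood_sd,
    hc_dep_rate = hc_dep_rate, patient_dep_rate = patient_dep_rate,
    bp_mania_rate = bp_mania_rate, rate_dispersion = rate_dispersion,
    ema_miss_primary = ema_miss_primary, ema_miss_both = ema_miss_both,
    cluster_radius_m = cluster_radius_m, tz_offset_h = tz_offset_h,
    start_date = as.Date(start_date), seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d HC / %d BP / %d MDD, %d days, duty %gs/%gs @ %g Hz, seed %d\n",
              x$n_hc, x$n_bp, x$n_mdd, x$n_days, x$on_s, x$off_s, x$rate_hz, x$seed))
  invisible(x)
}

# EMA cut-points on the latent mood scale. The first cut is placed so a
# control (latent ~ N(0, hc_mood_sd)) exceeds it on `hc_dep_rate` of days;
# higher categories are fixed offsets above it.
ema_cutpoints <- function(config) {
  c1 <- config$hc_mood_sd * qnorm(1 - config$hc_dep_rate)
  c(c1, c1 + 0.8, c1 + 1.6, c1 + 2.4)
}

# Discretize a latent mood value into an integer 1-5 EMA score.
discretize_ema <- function(latent, cuts) {
  pmin(5L, 1L + findInterval(latent, cuts))
}
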