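#' Generate a synthetic cohort of participants
#'
#' Draws participant-level covariates (age, sex, employment, antidepressant
#' use), three location-cluster centers (home, work, other; pairwise at least
#' 200 m apart), and a baseline mobility scale for each participant of a
#' three-group mood-disorder cohort.
#'
#' @param config a [cohort_config()].
#' @return a data.frame with one row per participant: `id`, `idx`, `group`
#'   (`"HC"`, `"BP"`, `"MDD"`), `age`, `sex` (`"F"`/`"M"`), `employment`,
#'   `antidepressant` (0/1), the three cluster centers in degrees
#'   (`home_lat` ... `other_lon`), `baseline_mobility_scale`, and
#'   `rate_shift` (per-participant logit shift of the mood-day rates).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stopf("'config' must be a cohort_config")
  n <- config$n_hc + config$n_bp + config$n_mdd
  group <- rep(c("HC", "BP", "MDD"), c(config$n_hc, config$n_bp, config$n_mdd))
  if (n == 0) {
    return(data.frame(id = character(), idx = integer(), group = character(),
                      age = numeric(), sex = character(), employment = character(),
                      antidepressant = integer(), home_lat = numeric(), home_lon = numeric(),
                      work_lat = numeric(), work_lon = numeric(), other_lat = numeric(),
                      other_lon = numeric(), baseline_mobility_scale = numeric(),
                      rate_shift = numeric(), stringsAsFactors = FALSE))
  }
  id <- sprintf("%s%02d", group, stats::ave(seq_len(n), group, FUN = seq_along))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(split_seed(config$seed, 101, i))
    age <- round(min(75, max(20, rnorm(1, 41, 12))))
    sex <- sample(c("F", "M"), 1, prob = c(0.63, 0.37))
    employment <- sample(c("unemployed", "employed", "student", "retired"), 1,
                         prob = c(0.2, 0.58, 0.12, 0.1))
    antidep <- if (group[i] == "HC") 0L else rbinom(1, 1, 0.7)
    # home somewhere in the Taipei basin; work/other at >= 200 m separation
    home_lat <- 25.03 + rnorm(1, 0, 0.03)
    home_lon <- 121.54 + rnorm(1, 0, 0.03)
    repeat {
      d_work <- runif(1, 800, 4000); th_w <- runif(1, 0, 2 * pi)
      d_oth <- runif(1, 400, 2500); th_o <- runif(1, 0, 2 * pi)
      w <- c(d_work * cos(th_w), d_work * sin(th_w))
      o <- c(d_oth * cos(th_o), d_oth * sin(th_o))
      if (sqrt(sum((w - o)^2)) >= 200) break
    }
    ll_w <- unproject_from_meters(w[1], w[2], home_lat, home_lon)
    ll_o <- unproject_from_meters(o[1], o[2], home_lat, home_lon)
    out[[i]] <- data.frame(
      id = id[i], idx = i, group = group[i], age = age, sex = sex,
      employment = employment, antidepressant = antidep,
      home_lat = round(home_lat, 8), home_lon = round(home_lon, 8),
      work_lat = round(ll_w$lat, 8), work_lon = round(ll_w$lon, 8),
      other_lat = round(ll_o$lat, 8), other_lon = round(ll_o$lon, 8),
      baseline_mobility_scale = round(rlnorm(1, 0, 0.25), 4),
      rate_shift = round(rnorm(1, 0, config$rate_dispersion), 4),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Latent mood deviation process for one participant across the follow-up.
# BP: sum of sinusoids at bp_periods (participant-specific phases);
# MDD: mean-reverting bounded walk with a spectrally flat stationary spread;
# HC: zero. `t_days` may be fractional (hourly emission reuses this).
mood_deviation <- function(participant, config, t_days) {
  group <- participant$group
  if (group == "BP") {
    set.seed(split_seed(config$seed, 202, participant$idx))
    phases <- runif(length(config$bp_periods), 0, 2 * pi)
    dev <- rep(0, length(t_days))
    for (j in seq_along(config$bp_periods))
      dev <- dev + config$bp_amplitude *
        sin(2 * pi * t_days / config$bp_periods[j] + phases[j])
    dev
  } else if (group == "MDD") {
    set.seed(split_seed(config$seed, 203, participant$idx))
    phi <- 0.9
    innov_sd <- config$mdd_amplitude * sqrt(1 - phi^2)
    dev <- numeric(length(t_days))
    m <- rnorm(1, 0, config$mdd_amplitude)
    for (k in seq_along(t_days)) {
      m <- phi * m + rnorm(1, 0, innov_sd)
      m <- max(-3 * config$mdd_amplitude, min(3 * config$mdd_amplitude, m))
      dev[k] <- m
    }
    dev
  } else {
    rep(0, length(t_days))
  }
}

# Marginal sd of the latent mood for a group (used to place baselines so the
# configured mood-day rates are met in expectation).
latent_sd <- function(group, config) {
  switch(group,
         HC = config$hc_mood_sd,
         BP = sqrt(length(config$bp_periods) * config$bp_amplitude^2 / 2 +
                     config$noise_sd^2),
         MDD = sqrt(config$mdd_amplitude^2 + config$noise_sd^2))
}

# Baseline placing P(latent > cut1) at `rate` given marginal sd.
baseline_for_rate <- function(rate, sdev, cut1) {
  if (rate <= 0) return(-Inf)
  cut1 - qnorm(1 - rate) * sdev
}

#' Simulate the daily mood / EMA series for one participant
#'
#' The latent mood (higher = more depressed) is the group deviation process
#' plus noise around a baseline placed so that the configured fraction of
#' days exceeds the first EMA cut-point (9% in controls, 44% in patients by
#' default). EMA items are monotone discretizations of item-specific latents
#' into 1-5; mania runs anti-phase to depression, fatigue and irritability are
#' attenuated copies. A configurable fraction of days misses the 12:45 primary
#' prompt (the 17:00 fallback is used) or both prompts.
#'
#' @param participant one row of [generate_cohort()].
#' @param config a [cohort_config()].
#' @return a data.frame with one row per day: `participant_id`, `day`,
#'   `date`, `latent_mood`, `mood_dev` (the oscillatory/aperiodic component),
#'   `ema_dep`, `ema_mania`, `ema_fatigue`, `ema_irrit` (integers 1-5 or NA),
#'   and `prompt` (`"primary"`, `"fallback"`, or NA).
#' @export
simulate_mood_series <- function(participant, config) {
  if (!inherits(config, "cohort_config")) stopf("'config' must be a cohort_config")
  if (config$n_days < 1) stopf("'n_days' must be >= 1")
  participant <- as.list(participant)
  nd <- config$n_days
  days <- seq_len(nd)
  cuts <- ema_cutpoints(config)
  dev <- mood_deviation(participant, config, days)
  sdev <- latent_sd(participant$group, config)
  shift <- participant$rate_shift %||% 0
  adj_rate <- function(r) if (r <= 0 || r >= 1) r else stats::plogis(stats::qlogis(r) + shift)

  dep_rate <- adj_rate(if (participant$group == "HC") config$hc_dep_rate else config$patient_dep_rate)
  mania_rate <- adj_rate(if (participant$group == "BP") config$bp_mania_rate else 0.08)
  fat_rate <- adj_rate(if (participant$group == "HC") 0.10 else 0.35)
  irr_rate <- adj_rate(if (participant$group == "HC") 0.08 else 0.30)
  item_noise_sd <- if (participant$group == "HC") config$hc_mood_sd else config$noise_sd

  set.seed(split_seed(config$seed, 204, participant$idx))
  latent <- baseline_for_rate(dep_rate, sdev, cuts[1]) + dev + rnorm(nd, 0, item_noise_sd)
  mania <- baseline_for_rate(mania_rate, sdev, cuts[1]) - dev + rnorm(nd, 0, item_noise_sd)
  sd_f <- sqrt((0.7 * sdev)^2 + item_noise_sd^2 * 0.51)
  fat <- baseline_for_rate(fat_rate, sd_f, cuts[1]) + 0.7 * dev + rnorm(nd, 0, item_noise_sd)
  sd_i <- sqrt((0.5 * sdev)^2 + item_noise_sd^2 * 0.75)
  irr <- baseline_for_rate(irr_rate, sd_i, cuts[1]) + 0.5 * dev + rnorm(nd, 0, item_noise_sd)

  u <- runif(nd)
  prompt <- ifelse(u < config$ema_miss_both, NA,
                   ifelse(u < config$ema_miss_both + config$ema_miss_primary,
                          "fallback", "primary"))
  miss <- is.na(prompt)
  score <- function(l) { s <- discretize_ema(l, cuts); s[miss] <- NA; as.integer(s) }
  data.frame(
    participant_id = participant$id, day = days,
    date = config$start_date + days - 1,
    latent_mood = latent, mood_dev = dev,
    ema_dep = score(latent), ema_mania = score(mania),
    ema_fatigue = score(fat), ema_irrit = score(irr),
    prompt = prompt, stringsAsFactors = FALSE)
}

# Random within-day visit schedule as waypoints (t seconds since local
# midnight; x/y meters relative to home). Mood couples multiplicatively into
# the number of excursions, the away-time fraction, and the novel-place
# probability; the BP/MDD deviation additionally amplitude-modulates the
# mobility scale so mobility features inherit the group's temporal structure.
make_day_schedule <- function(participant, mood, config) {
  me <- config$mood_effect
  m_units <- if (!is.na(mood$ema_dep)) max(0, mood$ema_dep - 1) else
    max(0, (mood$latent_mood - ema_cutpoints(config)[1]) / 0.8)
  amp_mult <- exp(-0.4 * mood$mood_dev)
  scale <- participant$baseline_mobility_scale * amp_mult * (1 - me[["scale"]])^m_units
  n_exc <- rpois(1, 3 * scale)
  day_s <- 86400
  if (n_exc == 0)
    return(data.frame(t = c(0, day_s), x = c(0, 0), y = c(0, 0)))
  away_frac <- min(0.8, 0.35 * amp_mult * (1 - me[["transition"]])^m_units)
  total_away <- day_s * away_frac
  away_i <- total_away * { w <- runif(n_exc, 0.5, 1.5); w / sum(w) }
  wd <- as.POSIXlt(mood$date)$wday
  is_weekday <- wd >= 1 && wd <= 5
  p_home <- project_to_meters(participant$home_lat, participant$home_lon,
                              participant$home_lat, participant$home_lon)
  dest <- vector("list", n_exc)
  for (k in seq_len(n_exc)) {
    if (k == 1 && is_weekday && participant$employment %in% c("employed", "student")) {
      pw <- project_to_meters(participant$work_lat, participant$work_lon,
                              participant$home_lat, participant$home_lon)
      dest[[k]] <- c(pw$x, pw$y)
    } else if (runif(1) < 0.4 * (1 - me[["diversity"]])^m_units) {
      d <- rlnorm(1, log(800), 0.6); th <- runif(1, 0, 2 * pi)
      dest[[k]] <- c(d * cos(th), d * sin(th))
    } else {
      po <- project_to_meters(participant$other_lat, participant$other_lon,
                              participant$home_lat, participant$home_lon)
      dest[[k]] <- c(po$x, po$y)
    }
  }
  # home gaps between excursions
  gap_w <- runif(n_exc + 1, 0.5, 1.5)
  gaps <- (day_s - total_away) * gap_w / sum(gap_w)
  t <- 0; wx <- 0; wy <- 0; wt <- 0
  for (k in seq_len(n_exc)) {
    t0 <- t + gaps[k]
    d <- dest[[k]]
    dist <- sqrt(sum(d^2))
    speed <- runif(1, 4, 10)
    tt <- dist / speed
    dwell <- max(away_i[k] - 2 * tt, 0)
    # compress travel if the away budget cannot cover the round trip
    if (away_i[k] < 2 * tt) tt <- away_i[k] / 2
    wt <- c(wt, t0, t0 + tt, t0 + tt + dwell, t0 + 2 * tt + dwell)
    wx <- c(wx, 0, d[1], d[1], 0)
    wy <- c(wy, 0, d[2], d[2], 0)
    t <- t0 + 2 * tt + dwell
  }
  wt <- c(wt, day_s); wx <- c(wx, 0); wy <- c(wy, 0)
  data.frame(t = wt, x = wx, y = wy)
}

#' Simulate one participant-day of duty-cycled GPS fixes
#'
#' Builds a continuous within-day path over the participant's location
#' clusters (excursion count, away time, and place diversity all shrink
#' multiplicatively with depressed mood), samples it at `rate_hz` during
#' duty-cycle on-periods, drops whole missing hours/days, adds isotropic
#' Gaussian noise, and draws a lognormal reported accuracy calibrated so a
#' configurable fraction exceeds 50 m.
#'
#' @param participant one row of [generate_cohort()].
#' @param mood the matching row of [simulate_mood_series()].
#' @param config a [cohort_config()].
#' @param schedule optional waypoint data.frame (`t` seconds since local
#'   midnight, `x`, `y` meters from home) overriding the random schedule;
#'   useful for controlled experiments.
#' @return a data.frame of fixes: `t` (UTC seconds), `lat`, `lon`,
#'   `altitude`, `accuracy` (m). Zero rows if the whole day is missing.
#' @export
simulate_day_trajectory <- function(participant, mood, config, schedule = NULL) {
  participant <- as.list(participant); mood <- as.list(mood)
  if (!is.null(mood$participant_id) && mood$participant_id != participant$id)
    stopf("mood row belongs to '%s', not participant '%s'",
          mood$participant_id, participant$id)
  set.seed(split_seed(config$seed, 205, participant$idx, mood$day))
  empty <- data.frame(t = numeric(), lat = numeric(), lon = numeric(),
                      altitude = numeric(), accuracy = numeric())
  if (is.null(schedule)) {
    if (runif(1) < config$missing_day_prob) return(empty)
    schedule <- make_day_schedule(participant, mood, config)
  }
  t_local <- seq(0, 86400 - 1 / config$rate_hz, by = 1 / config$rate_hz)
  keep <- (t_local %% (config$on_s + config$off_s)) < config$on_s
  t_local <- t_local[keep]
  if (config$missing_hour_prob > 0) {
    drop_h <- which(runif(24) < config$missing_hour_prob) - 1
    if (length(drop_h)) t_local <- t_local[!(floor(t_local / 3600) %in% drop_h)]
  }
  if (!length(t_local)) return(empty)
  x <- approx(schedule$t, schedule$x, xout = t_local, rule = 2)$y +
    rnorm(length(t_local), 0, config$gps_noise_sd)
  y <- approx(schedule$t, schedule$y, xout = t_local, rule = 2)$y +
    rnorm(length(t_local), 0, config$gps_noise_sd)
  ll <- unproject_from_meters(x, y, participant$home_lat, participant$home_lon)
  sdlog <- 0.5
  meanlog <- log(50) - sdlog * qnorm(1 - config$accuracy_tail_prob)
  acc <- rlnorm(length(t_local), meanlog, sdlog)
  day_start_utc <- as.numeric(as.POSIXct(as.Date(mood$date), tz = "UTC")) -
    config$tz_offset_h * 3600
  data.frame(t = day_start_utc + t_local,
             lat = round(ll$lat, 8), lon = round(ll$lon, 8),
             altitude = 0, accuracy = round(acc, 3))
}

#' Apply a duty-cycle mask to GPS fixes
#'
#' Keeps exactly the fixes whose offset within each `(on_s + off_s)` cycle,
#' anchored at `day_start`, falls inside the on-period.
#'
#' @param fixes data.frame with a numeric time column `t`, time-sorted.
#' @param on_s,off_s on/off durations in seconds.
#' @param day_start cycle anchor (seconds); defaults to the UTC midnight at or
#'   before the first fix.
#' @return the retained fixes, order preserved.
#' @export
apply_duty_cycle <- function(fixes, on_s, off_s, day_start = NULL) {
  check_pos(on_s, "on_s"); check_pos(off_s, "off_s", strict = FALSE)
  if (nrow(fixes) == 0) return(fixes)
  if (is.unsorted(fixes$t)) stopf("'fixes' must be time-sorted")
  if (is.null(day_start)) day_start <- floor(min(fixes$t) / 86400) * 86400
  fixes[((fixes$t - day_start) %% (on_s + off_s)) < on_s, , drop = FALSE]
}

#' Expected GPS fixes per hour under a duty cycle
#'
#' The long-run average number of fixes collected per hour when sampling at
#' `rate_hz` during each on-period: `3600 / (on_s + off_s) * on_s * rate_hz`,
#' fractional final cycle credited proportionally, rounded to the nearest
#' integer. A 60 s on / 600 s off cycle at 1 Hz yields 327 fixes per hour.
#'
#' @param on_s,off_s on/off durations in seconds.
#' @param rate_hz sampling rate during the on-period.
#' @return integer fixes per hour.
#' @export
expected_fix_count <- function(on_s, off_s, rate_hz) {
  check_pos(on_s, "on_s"); check_pos(off_s, "off_s", strict = FALSE)
  check_pos(rate_hz, "rate_hz")
  as.integer(round(3600 / (on_s + off_s) * on_s * rate_hz))
}
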