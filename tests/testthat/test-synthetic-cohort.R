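test_that("cohort generation honors group counts, labels, and determinism", {
  cfg <- cohort_config(n_hc = 15, n_bp = 20, n_mdd = 27, n_days = 28, seed = 7)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 62)
  expect_setequal(unique(coh$group), c("HC", "BP", "MDD"))
  expect_equal(unname(table(coh$group)[c("HC", "BP", "MDD")]), c(15L, 20L, 27L),
               ignore_attr = TRUE)
  expect_equal(nrow(generate_cohort(cohort_config(0, 0, 0, seed = 1))), 0)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("cohort cluster centers are pairwise at least 200 m apart", {
  cfg <- cohort_config(n_hc = 5, n_bp = 5, n_mdd = 5, n_days = 28, seed = 3)
  coh <- generate_cohort(cfg)
  for (i in seq_len(nrow(coh))) {
    p <- coh[i, ]
    pts <- project_to_meters(c(p$home_lat, p$work_lat, p$other_lat),
                             c(p$home_lon, p$work_lon, p$other_lon),
                             p$home_lat, p$home_lon)
    d <- as.matrix(dist(pts))
    expect_true(all(d[upper.tri(d)] >= 200 - 1e-6))
  }
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(n_hc = -1), "n_hc")
  expect_error(cohort_config(missing_day_prob = 1.2), "missing_day_prob")
  expect_error(cohort_config(on_s = 0), "on_s")
  expect_error(cohort_config(rate_hz = -1), "rate_hz")
  expect_error(cohort_config(n_days = 14, bp_periods = c(1, 9)), "bp_periods")
})

test_that("control EMA calibration hits the configured 9% mood-day rate", {
  cfg <- cohort_config(n_hc = 10, n_bp = 0, n_mdd = 0, n_days = 150, seed = 21)
  coh <- generate_cohort(cfg)
  moods <- do.call(rbind, lapply(seq_len(nrow(coh)), function(i)
    simulate_mood_series(coh[i, ], cfg)))
  scored <- moods$ema_dep[!is.na(moods$ema_dep)]
  expect_gte(length(scored), 1000)
  rate <- mean(scored > 1)
  expect_lt(abs(rate - 0.09), 0.03)
})

test_that("latent mood is constant when amplitude and noise are zero", {
  cfg <- cohort_config(n_hc = 0, n_bp = 1, n_mdd = 0, n_days = 28,
                       bp_amplitude = 0, noise_sd = 0, seed = 2)
  coh <- generate_cohort(cfg)
  moods <- simulate_mood_series(coh[1, ], cfg)
  expect_equal(var(moods$latent_mood), 0)
})

test_that("a single 4-day cycle dominates the mood autocorrelation at lag 4", {
  cfg <- cohort_config(n_hc = 0, n_bp = 3, n_mdd = 0, n_days = 56,
                       bp_periods = 4, noise_sd = 0, seed = 9)
  coh <- generate_cohort(cfg)
  for (i in seq_len(nrow(coh))) {
    moods <- simulate_mood_series(coh[i, ], cfg)
    ac <- vapply(2:14, function(l) oracle_autocorr(moods$latent_mood, l), 1)
    expect_equal((2:14)[which.max(ac)], 4)
  }
})

test_that("mobility scale zero keeps every fix within the noise radius of home", {
  cfg <- cohort_config(n_hc = 1, n_bp = 0, n_mdd = 0, n_days = 28,
                       missing_day_prob = 0, gps_noise_sd = 3, seed = 5)
  coh <- generate_cohort(cfg)
  p <- coh[1, ]; p$baseline_mobility_scale <- 0
  moods <- simulate_mood_series(p, cfg)
  fx <- simulate_day_trajectory(p, moods[2, ], cfg)
  pr <- project_to_meters(fx$lat, fx$lon, p$home_lat, p$home_lon)
  expect_true(all(sqrt(pr$x^2 + pr$y^2) < 6 * cfg$gps_noise_sd))
})

test_that("duty-cycled sampling averages 327 fixes per hour at 60/600 s, 1 Hz", {
  cfg <- cohort_config(n_hc = 1, n_bp = 0, n_mdd = 0, n_days = 28,
                       missing_day_prob = 0, missing_hour_prob = 0, seed = 4)
  coh <- generate_cohort(cfg)
  moods <- simulate_mood_series(coh[1, ], cfg)
  fx <- simulate_day_trajectory(coh[1, ], moods[1, ], cfg)
  # 11 hours = 60 whole 660-s cycles, so the per-hour average is exact
  day_start <- min(fx$t)
  n11 <- sum(fx$t < day_start + 11 * 3600)
  expect_equal(round(n11 / 11), expected_fix_count(60, 600, 1))
})

test_that("a noise-free round trip has path length twice the one-way distance", {
  cfg <- cohort_config(n_hc = 1, n_bp = 0, n_mdd = 0, n_days = 28,
                       gps_noise_sd = 0, missing_day_prob = 0,
                       missing_hour_prob = 0, seed = 8)
  coh <- generate_cohort(cfg)
  p <- coh[1, ]
  moods <- simulate_mood_series(p, cfg)
  pw <- project_to_meters(p$work_lat, p$work_lon, p$home_lat, p$home_lon)
  d <- sqrt(pw$x^2 + pw$y^2)
  sched <- data.frame(t = c(0, 30000, 32000, 50000, 52000, 86400),
                      x = c(0, 0, pw$x, pw$x, 0, 0),
                      y = c(0, 0, pw$y, pw$y, 0, 0))
  fx <- simulate_day_trajectory(p, moods[1, ], cfg, schedule = sched)
  pr <- project_to_meters(fx$lat, fx$lon, p$home_lat, p$home_lon)
  path <- sum(sqrt(diff(pr$x)^2 + diff(pr$y)^2))
  expect_lt(abs(path - 2 * d) / (2 * d), 0.01)
})

test_that("apply_duty_cycle keeps exactly the modular on-cycle fixes", {
  fx <- data.frame(t = 0:3599, lat = 0, lon = 0, accuracy = 10)
  expect_identical(apply_duty_cycle(fx, 60, 0), fx)
  kept <- apply_duty_cycle(fx, 60, 600, day_start = 0)
  expect_true(all((kept$t %% 660) < 60))
  expect_equal(nrow(kept), sum((0:3599 %% 660) < 60))
  expect_error(apply_duty_cycle(fx, -5, 600), "on_s")
})

test_that("whole-cycle duty-cycle counts match the expected rate within 1", {
  for (par in list(c(60, 600), c(30, 570), c(45, 255), c(60, 0), c(10, 110))) {
    on <- par[1]; off <- par[2]
    n_cycles <- 20
    fx <- data.frame(t = seq(0, n_cycles * (on + off) - 1), accuracy = 10)
    kept <- apply_duty_cycle(fx, on, off, day_start = 0)
    expected <- expected_fix_count(on, off, 1) * n_cycles * (on + off) / 3600
    expect_lte(abs(nrow(kept) - expected), 1)
  }
})

test_that("expected_fix_count reproduces the duty-cycle arithmetic", {
  expect_equal(expected_fix_count(60, 600, 1), 327L)
  expect_equal(expected_fix_count(60, 0, 1), 3600L)
  expect_equal(expected_fix_count(30, 570, 1), 180L)
  expect_error(expected_fix_count(0, 600, 1), "on_s")
  expect_error(expected_fix_count(60, 600, 0), "rate_hz")
})

test_that("Beiwe CSV files round-trip losslessly", {
  cfg <- cohort_config(n_hc = 1, n_bp = 0, n_mdd = 0, n_days = 28,
                       missing_day_prob = 0, seed = 6)
  coh <- generate_cohort(cfg)
  moods <- simulate_mood_series(coh[1, ], cfg)
  fx <- simulate_day_trajectory(coh[1, ], moods[1, ], cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_beiwe_csv(fx, path)
  expect_equal(length(readLines(path)), nrow(fx) + 1)
  back <- read_beiwe_csv(path)
  rownames(back) <- NULL
  expect_equal(back, fx[order(fx$t), ], tolerance = 1e-12)
  # empty list -> header-only file
  write_beiwe_csv(fx[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_beiwe_csv(path)), 0)
})

test_that("trajectories are deterministic given the config seed", {
  cfg <- cohort_config(n_hc = 1, n_bp = 1, n_mdd = 1, n_days = 28, seed = 13)
  coh <- generate_cohort(cfg)
  moods <- simulate_mood_series(coh[2, ], cfg)
  expect_identical(simulate_day_trajectory(coh[2, ], moods[5, ], cfg),
                   simulate_day_trajectory(coh[2, ], moods[5, ], cfg))
  expect_identical(simulate_mood_series(coh[3, ], cfg),
                   simulate_mood_series(coh[3, ], cfg))
})

test_that("depressed days depress mobility by construction", {
  # noiseless feature-level check of the multiplicative mood coupling
  pd <- simulate_person_days(n_participants = 30, n_days = 60, seed = 17)
  wk <- pd[pd$weekday, ]
  expect_lt(mean(wk$lv[wk$depressed]), mean(wk$lv[!wk$depressed]))
  expect_lt(mean(wk$tt[wk$depressed]), mean(wk$tt[!wk$depressed]))
  we <- pd[!pd$weekday, ]
  expect_lt(mean(we$entropy[we$depressed]), mean(we$entropy[!we$depressed]))
})
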