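test_that("mood-fluctuation rates reproduce the worked percentages", {
  mk <- function(pos, tot) data.frame(depressed = c(rep(TRUE, pos),
                                                    rep(FALSE, tot - pos)))
  expect_equal(round(mood_fluctuation_rate(mk(1577, 3584), "depressed")$percent), 44)
  expect_equal(round(mood_fluctuation_rate(mk(716, 1504), "depressed")$percent), 48)
  expect_equal(round(mood_fluctuation_rate(mk(103, 1148), "depressed")$percent), 9)
  expect_equal(round(mood_fluctuation_rate(mk(23, 47), "depressed")$percent, 1), 48.9)
  # score form: all items 1 means no mood days
  ones <- data.frame(ema_dep = rep(1L, 50))
  expect_equal(mood_fluctuation_rate(ones, "ema_dep")$percent, 0)
  expect_error(mood_fluctuation_rate(data.frame(ema_dep = NA_integer_), "ema_dep"),
               "no scored days")
})

test_that("Kruskal-Wallis matches the rank formula and handles full ties", {
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5, 5)))$H, 0)
  expect_equal(kruskal_wallis(list(1:3, 4:6, 7:9))$H, 7.2)
  for (s in 1:100) {
    set.seed(s)
    samples <- lapply(1:3, function(i) sample(1:8, sample(3:7, 1), replace = TRUE))
    expect_equal(kruskal_wallis(samples)$H, oracle_kruskal(samples),
                 tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "nonempty")
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(11)
  samples <- lapply(1:3, function(i) runif(10))
  h0 <- kruskal_wallis(samples)$H
  expect_equal(kruskal_wallis(lapply(samples, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(samples, function(x) x^3 + 2))$H, h0)
})

test_that("Mann-Whitney U, mean ranks, and ties match enumeration", {
  m <- mann_whitney_mean_ranks(c(1, 2), c(3, 4))
  expect_equal(m$U, 0)
  expect_equal(m$mean_rank_a, 1.5)
  expect_equal(m$mean_rank_b, 3.5)
  same <- mann_whitney_mean_ranks(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_rank_a, same$mean_rank_b)
  for (s in 1:100) {
    set.seed(s)
    a <- sample(1:6, sample(2:8, 1), replace = TRUE)
    b <- sample(1:6, sample(2:8, 1), replace = TRUE)
    m <- mann_whitney_mean_ranks(a, b)
    expect_equal(m$U, oracle_mann_whitney_U(a, b))  # U counts a-above-b pairs
    # rank-sum identity over the pooled ranking
    N <- length(a) + length(b)
    expect_equal(length(a) * m$mean_rank_a + length(b) * m$mean_rank_b,
                 N * (N + 1) / 2)
    # p agrees with the normal-approximation reference implementation
    ref <- suppressWarnings(wilcox.test(a, b, correct = FALSE, exact = FALSE))
    expect_equal(m$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the printed group mean ranks satisfy the rank-sum identity", {
  # 12 and 19 participants: 12 * 20.17 + 19 * 13.37 ~ 496 = 31 * 32 / 2
  expect_equal(12 * 20.17 + 19 * 13.37, 496, tolerance = 0.002)
})

test_that("timescale correlations behave at the edges and favor daily coupling", {
  lin <- data.frame(participant_id = "P", day = 1:30, ema = 1:30, lv = 2 * (1:30))
  expect_equal(correlate_by_timescale(lin, "lv", window = "daily")$r, 1)
  const <- data.frame(participant_id = "P", day = 1:30, ema = rnorm(30), lv = 5)
  res <- correlate_by_timescale(const, "lv", window = "daily")
  expect_true(res$undefined)
  expect_true(is.na(res$r))
  ok <- 0
  for (s in 1:20) {
    d <- simulate_coupled_series(n_participants = 8, n_days = 180, seed = s)
    rd <- correlate_by_timescale(d, "lv", window = "daily")$r
    rm <- correlate_by_timescale(d, "lv", window = "monthly")$r
    if (abs(rd) > abs(rm)) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("VIF pruning drops collinear features and matches brute force", {
  set.seed(4)
  X <- data.frame(a = rnorm(100), c = rnorm(100))
  X$b <- X$a
  kept <- vif_prune(X[c("a", "b", "c")])
  expect_equal(length(kept), 2)
  expect_true("c" %in% kept)
  expect_equal(sum(c("a", "b") %in% kept), 1)
  ortho <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  expect_equal(sort(as.character(vif_prune(ortho))), c("a", "b", "c"))
  for (s in 1:100) {
    set.seed(s)
    n <- 60
    z <- rnorm(n)
    M <- data.frame(a = z + rnorm(n, 0, 0.8), b = z + rnorm(n, 0, 0.8),
                    c = rnorm(n))
    expect_equal(unname(gpsrhythms:::vif_values(M)), unname(oracle_vif(M)),
                 tolerance = 1e-8)
  }
})

test_that("day-level logistic models recover the planted mobility effects", {
  pd <- simulate_person_days(n_participants = 62, n_days = 84, seed = 11)
  expect_gte(nrow(pd), 3000)
  m <- fit_daylevel_logistic(pd, "weekday")
  for (f in c("lv", "tt")) {
    r <- m$terms[m$terms$term == f, ]
    expect_lt(r$or, 1)
    expect_lt(r$ci_hi, 1)
  }
  me <- fit_daylevel_logistic(pd, "weekend")
  expect_lt(me$terms$or[me$terms$term == "entropy"], 1)
  # degenerate outcome errors out
  pd0 <- pd; pd0$depressed <- FALSE
  expect_error(fit_daylevel_logistic(pd0, "all"), "outcome")
})

test_that("null-generator confidence intervals cover OR = 1 near 95%", {
  cover <- 0
  B <- 60
  for (b in seq_len(B)) {
    pd <- simulate_person_days(n_participants = 20, n_days = 30,
                               weekday_lv_effect = 0, weekday_tt_effect = 0,
                               weekend_entropy_effect = 0, seed = 1000 + b)
    m <- fit_daylevel_logistic(pd, "weekday", features = "lv")
    r <- m$terms[m$terms$term == "lv", ]
    if (r$ci_lo <= 1 && r$ci_hi >= 1) cover <- cover + 1
  }
  expect_gt(cover / B, 0.85)
  expect_lte(cover / B, 1)
})

test_that("logistic fits are invariant to covariate centering", {
  pd <- simulate_person_days(n_participants = 30, n_days = 40, seed = 3)
  m1 <- fit_daylevel_logistic(pd, "all", features = c("lv", "tt"))
  pd2 <- pd; pd2$age <- pd2$age - mean(pd2$age)
  m2 <- fit_daylevel_logistic(pd2, "all", features = c("lv", "tt"))
  for (f in c("lv", "tt", "age")) {
    expect_equal(m1$terms$or[m1$terms$term == f],
                 m2$terms$or[m2$terms$term == f], tolerance = 1e-6)
  }
})

test_that("spectrum models are affine-equivariant and consistent across sets", {
  set.seed(9)
  n <- 120
  pw <- data.frame(power = c(rnorm(n / 2, 60, 20), rnorm(n / 2, 40, 20)),
                   depressed = rep(c(FALSE, TRUE), each = n / 2),
                   age = rnorm(n, 40, 10), sex = sample(c("F", "M"), n, TRUE),
                   employee_or_student = rbinom(n, 1, 0.6),
                   antidepressant = rbinom(n, 1, 0.5))
  m1 <- fit_spectrum_logistic(pw, "power", "depressed", model = 1)
  b1 <- m1$terms$beta[m1$terms$term == "power"]
  pw2 <- pw; pw2$power <- pw2$power * 100
  m1b <- fit_spectrum_logistic(pw2, "power", "depressed", model = 1)
  expect_equal(m1b$terms$beta[m1b$terms$term == "power"], b1 / 100,
               tolerance = 1e-6)
  expect_equal(attr(m1b, "or_per_sd"), attr(m1, "or_per_sd"), tolerance = 1e-6)
  # covariates independent of the outcome: model 4 OR close to model 1
  m4 <- fit_spectrum_logistic(pw, "power", "depressed", model = 4)
  expect_equal(m4$terms$or[m4$terms$term == "power"],
               m1$terms$or[m1$terms$term == "power"], tolerance = 0.01)
  expect_error(fit_spectrum_logistic(pw, "power", "depressed", model = 7),
               "model")
})

test_that("complete separation raises a named error", {
  dd <- data.frame(power = c(1:20, 101:120),
                   depressed = rep(c(FALSE, TRUE), each = 20),
                   age = rnorm(40, 40, 5), sex = "F",
                   employee_or_student = 1, antidepressant = 0)
  expect_error(fit_spectrum_logistic(dd, "power", "depressed", model = 1),
               "separation")
})

test_that("the Fisher-z sample-size formula reproduces its reference values", {
  expect_equal(sample_size_correlation(0.5, 0.05, 0.90), 38L)
  expect_equal(sample_size_correlation(0.5, 0.05, 0.80), 30L)
  expect_equal(sample_size_correlation(0.9999, 0.05, 0.90), 4L)
  expect_error(sample_size_correlation(1.2, 0.05, 0.9), "'r'")
  expect_error(sample_size_correlation(0.5, 0, 0.9), "'alpha'")
  expect_error(sample_size_correlation(0.5, 0.05, 1), "'power'")
})

test_that("the person-day table joins features, EMA flags, and covariates", {
  cfg <- cohort_config(n_hc = 1, n_bp = 1, n_mdd = 0, n_days = 28, seed = 2)
  coh <- generate_cohort(cfg)
  feats <- data.frame(participant_id = rep(coh$id, each = 3),
                      date = rep(cfg$start_date + 0:2, 2),
                      lv = rnorm(6), tt = runif(6), included = TRUE)
  ema <- data.frame(participant_id = rep(coh$id, each = 3),
                    date = rep(cfg$start_date + 0:2, 2),
                    ema_dep = c(1, 3, NA, 2, 1, 1), ema_mania = 1,
                    ema_fatigue = 1, ema_irrit = 1)
  pd <- person_day_table(feats, ema, coh)
  expect_equal(nrow(pd), 6)
  expect_equal(sum(pd$depressed, na.rm = TRUE), 2)
  expect_true(any(is.na(pd$depressed)))
  expect_true(all(c("weekday", "employee_or_student", "age", "sex") %in% names(pd)))
  # 2020-01-01 was a Wednesday; 2020-01-04 a Saturday
  expect_true(pd$weekday[pd$date == as.Date("2020-01-01")][1])
})
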