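test_that("accuracy filtering keeps fixes at or under the threshold", {
  fx <- data.frame(t = 1:5, accuracy = c(10, 49, 50, 51, 80))
  expect_equal(filter_accuracy(fx)$accuracy, c(10, 49, 50))
  expect_equal(nrow(filter_accuracy(fx[0, ])), 0)
  ok <- data.frame(t = 1:3, accuracy = c(5, 20, 50))
  expect_identical(filter_accuracy(ok), ok)
})

test_that("relaxing the accuracy threshold never drops a retained fix", {
  set.seed(1)
  fx <- data.frame(t = 1:200, accuracy = runif(200, 1, 120))
  for (thr in c(20, 50, 80)) {
    tight <- filter_accuracy(fx, thr)
    loose <- filter_accuracy(fx, thr + 25)
    expect_true(all(tight$t %in% loose$t))
  }
})

test_that("10-second binning averages fixes and flags silent bins invalid", {
  pts <- data.frame(t = 0:9, x = 5, y = -3)
  b <- bin_10s(pts, day_start = 0, n_bins = 6)
  expect_equal(sum(b$valid), 1)
  expect_equal(b$x[1], 5); expect_equal(b$y[1], -3)
  # a 15-s silence leaves the empty bin invalid
  pts2 <- data.frame(t = c(0:9, 25:30), x = 1, y = 1)
  b2 <- bin_10s(pts2, day_start = 0, n_bins = 4)
  expect_false(b2$valid[2])
  expect_true(all(is.na(b2$x[!b2$valid])))
})

test_that("bin means equal brute-force group-by means on random data", {
  for (s in 1:100) {
    set.seed(s)
    pts <- data.frame(t = runif(60, 0, 300), x = rnorm(60), y = rnorm(60))
    b <- bin_10s(pts, day_start = 0, n_bins = 30)
    o <- oracle_bin_means(pts, 0, 30)
    expect_equal(b$x, o$x, tolerance = 1e-12)
    expect_equal(b$y, o$y, tolerance = 1e-12)
    expect_equal(b$valid, !is.na(o$x))
  }
})

make_bins <- function(x, y, valid = rep(TRUE, length(x))) {
  data.frame(bin_start = (seq_along(x) - 1) * 10, x = ifelse(valid, x, NA),
             y = ifelse(valid, y, NA), n = as.integer(valid), valid = valid)
}

test_that("the per-10s displacement rule separates stationary from moving", {
  b_slow <- make_bins(x = (0:20) * 1, y = rep(0, 21))
  seg <- classify_states(b_slow)
  expect_equal(seg$state, "stationary")
  b_fast <- make_bins(x = (0:20) * 5, y = rep(0, 21))
  expect_equal(classify_states(b_fast)$state, "moving")
  # the rule is strictly "exceeds": displacement just under sqrt(10) stays
  b_edge <- make_bins(x = (0:10) * 3.16, y = rep(0, 11))
  expect_equal(classify_states(b_edge)$state, "stationary")
})

test_that("unknown runs resolve by the windowed 75 m displacement rule", {
  # 5-minute gap with endpoints 80 m apart -> movement
  valid <- c(rep(TRUE, 3), rep(FALSE, 29), rep(TRUE, 3))
  x <- c(0, 0, 0, rep(NA, 29), 80, 80, 80)
  b <- make_bins(x = ifelse(is.na(x), 0, x), y = rep(0, 35), valid = valid)
  seg <- classify_states(b)
  expect_true("moving" %in% seg$state)
  # same displacement spread over 2 hours -> stationary
  valid2 <- c(rep(TRUE, 3), rep(FALSE, 720), rep(TRUE, 3))
  b2 <- make_bins(x = c(0, 0, 0, rep(0, 720), 80, 80, 80),
                  y = rep(0, 726), valid = valid2)
  expect_false("moving" %in% classify_states(b2)$state)
})

test_that("state segments partition observed time and match the rule oracle", {
  for (s in 1:100) {
    set.seed(s)
    n <- 50
    valid <- runif(n) > 0.3
    if (sum(valid) < 2) next
    b <- make_bins(x = cumsum(rnorm(n, 0, 4)), y = cumsum(rnorm(n, 0, 4)),
                   valid = valid)
    seg <- classify_states(b)
    expect_equal(sum(seg$end - seg$start), n * 10)
    expect_true(all(seg$end > seg$start))
    # per-step states agree with the direct transcription of the rules
    st <- oracle_states(b)
    idx <- findInterval(b$bin_start[-n], seg$start)
    expect_equal(seg$state[idx], st)
  }
})

test_that("state classification is invariant to translation and rotation", {
  set.seed(42)
  n <- 80
  b <- make_bins(x = cumsum(rnorm(n, 0, 4)), y = cumsum(rnorm(n, 0, 4)),
                 valid = runif(n) > 0.2)
  ref <- classify_states(b)$state
  th <- 1.1
  b_rot <- b
  b_rot$x <- cos(th) * b$x - sin(th) * b$y + 500
  b_rot$y <- sin(th) * b$x + cos(th) * b$y - 900
  expect_equal(classify_states(b_rot)$state, ref)
})

test_that("gap imputation preserves valid bins and centers on the interpolant", {
  full <- make_bins(x = 1:30, y = 31:60)
  sims <- impute_gaps(full, n_sim = 5, jitter_sd = 3, seed = 1)
  for (s in sims) expect_identical(s, full)
  gappy <- make_bins(x = 1:30, y = rep(0, 30),
                     valid = !(seq_len(30) %in% 10:20))
  sims <- impute_gaps(gappy, n_sim = 400, jitter_sd = 3, seed = 2)
  mids <- vapply(sims, function(s) s$x[15], 1)
  expect_true(all(vapply(sims, function(s) all(s$valid), TRUE)))
  # valid bins untouched in every completion
  for (s in sims[1:5]) expect_equal(s$x[gappy$valid], gappy$x[gappy$valid])
  se <- sd(mids) / sqrt(length(mids))
  expect_lt(abs(mean(mids) - 15), 3 * se + 1e-9)
  expect_error(impute_gaps(make_bins(1, 1, valid = TRUE)), "uninterpolatable")
})

test_that("long leading gaps are filled from a donor day's clock bins", {
  n <- 60
  target <- make_bins(x = rep(0, n), y = rep(0, n),
                      valid = c(rep(FALSE, 40), rep(TRUE, 20)))
  donor <- make_bins(x = rep(7, n), y = rep(9, n))
  sims <- impute_gaps(target, n_sim = 2, jitter_sd = 0, donor = donor, seed = 1)
  expect_true(all(sims[[1]]$valid))
  expect_equal(sims[[1]]$x[1:40], rep(7, 40))
  # without a donor the edge gap stays invalid
  sims2 <- impute_gaps(target, n_sim = 1, jitter_sd = 0, seed = 1)
  expect_false(any(sims2[[1]]$valid[1:40]))
})

test_that("day validity counts hours with data and applies the 6-hour rule", {
  full <- data.frame(bin_start = (0:8639) * 10, valid = TRUE)
  v <- day_validity(full)
  expect_equal(v$valid_hours, 24)
  expect_true(v$included)
  five <- data.frame(bin_start = (0:8639) * 10,
                     valid = (0:8639 * 10) < 5 * 3600)
  expect_false(day_validity(five)$included)
  for (s in 1:50) {
    set.seed(s)
    mask <- runif(8640) < 0.002
    b <- data.frame(bin_start = (0:8639) * 10, valid = mask)
    expect_equal(day_validity(b)$valid_hours,
                 length(unique(floor((0:8639) * 10 / 3600)[mask])))
  }
})

test_that("daily EMA resolution prefers the primary prompt", {
  long <- function(...) {
    d <- data.frame(...)
    d$participant_id <- rep("P", nrow(d)); d
  }
  both <- long(prompt = c("primary", "fallback"), item = "dep", score = c(3L, 2L))
  expect_equal(resolve_daily_ema(both)[["dep"]], 3L)
  fb <- long(prompt = "fallback", item = "dep", score = 2L)
  expect_equal(resolve_daily_ema(fb)[["dep"]], 2L)
  none <- long(prompt = character(), item = character(), score = integer())
  expect_true(all(is.na(resolve_daily_ema(none))))
  bad <- long(prompt = "primary", item = "dep", score = 7L)
  expect_error(resolve_daily_ema(bad), "1..5")
})
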