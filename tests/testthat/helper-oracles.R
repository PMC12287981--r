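# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as direct transcriptions of the defining
# formulas, sharing no code with the package internals.

oracle_bin_means <- function(points, day_start, n_bins, bin_s = 10) {
  out <- data.frame(bin = seq_len(n_bins), x = NA_real_, y = NA_real_)
  for (b in seq_len(n_bins)) {
    lo <- day_start + (b - 1) * bin_s
    sel <- points$t >= lo & points$t < lo + bin_s
    if (any(sel)) {
      out$x[b] <- mean(points$x[sel])
      out$y[b] <- mean(points$y[sel])
    }
  }
  out
}

oracle_kruskal <- function(samples) {
  x <- unlist(samples)
  g <- rep(seq_along(samples), vapply(samples, length, 1L))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

oracle_mann_whitney_U <- function(a, b) {
  # pairwise enumeration definition of U for sample a
  U <- 0
  for (ai in a) for (bi in b) U <- U + (ai > bi) + 0.5 * (ai == bi)
  U
}

oracle_vif <- function(X) {
  X <- as.data.frame(X)
  vapply(seq_along(X), function(i) {
    r2 <- summary(lm(X[[i]] ~ ., data = X[-i]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

oracle_top_k <- function(power, frequency, k, step, window) {
  period <- 1 / frequency
  keep <- which(period >= 2 * step & period <= window / 2)
  ord <- keep[order(-power[keep], frequency[keep])]
  head(ord, k)
}

oracle_entropy <- function(dwell) {
  p <- dwell / sum(dwell)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_lv <- function(x, y) {
  pv <- function(v) sum((v - mean(v))^2) / length(v)
  log(pv(x) + pv(y) + 1e-6)
}

oracle_autocorr <- function(x, lag) {
  n <- length(x)
  xc <- x - mean(x)
  sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / sum(xc^2)
}

# direct transcription of the state rules, step by step
oracle_states <- function(bins, thr = sqrt(10), gap_thr = 75, gap_win = 360) {
  n <- nrow(bins)
  bin_s <- bins$bin_start[2] - bins$bin_start[1]
  st <- character(n - 1)
  for (i in seq_len(n - 1)) {
    if (bins$valid[i] && bins$valid[i + 1]) {
      d <- sqrt((bins$x[i + 1] - bins$x[i])^2 + (bins$y[i + 1] - bins$y[i])^2)
      st[i] <- if (d > thr) "moving" else "stationary"
    } else st[i] <- "unknown"
  }
  i <- 1
  while (i <= n - 1) {
    if (st[i] == "unknown") {
      j <- i
      while (j < n - 1 && st[j + 1] == "unknown") j <- j + 1
      if (bins$valid[i] && bins$valid[j + 1]) {
        span <- (j + 1 - i) * bin_s
        d <- sqrt((bins$x[j + 1] - bins$x[i])^2 + (bins$y[j + 1] - bins$y[i])^2)
        eff <- d * min(1, gap_win / span)
        st[i:j] <- if (eff >= gap_thr) "moving" else "stationary"
      }
      i <- j + 1
    } else i <- i + 1
  }
  st
}

# stationary bins on a square-ish random day used by several feature tests
random_valid_bins <- function(n = 120, sd_pos = 40, seed = 1) {
  set.seed(seed)
  data.frame(bin_start = (seq_len(n) - 1) * 10,
             x = rnorm(n, 0, sd_pos), y = rnorm(n, 0, sd_pos),
             n = 1L, valid = TRUE)
}
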