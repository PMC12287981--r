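#' Power spectrum of a regular feature series
#'
#' Plain discrete Fourier transform of a gap-free, mean-removed series;
#' power is the squared magnitude divided by the series length, so the total
#' power over all bins (DC included) equals the sum of squares of the series
#' (Parseval). The DC bin is excluded from the returned spectrum; frequencies
#' are in cycles per day up to the Nyquist limit `1 / (2 * step_days)`.
#'
#' @param series numeric vector (length >= 8, no NA, mean-removed) or a
#'   [build_feature_series()] object.
#' @param step_days sampling step in days (ignored when `series` is a
#'   `feature_series`).
#' @param taper `"rectangular"` (default, a plain transform) or `"hann"`.
#' @return object of class `gps_spectrum`: list with `frequency` (cycles/day,
#'   ascending), `power`, `step_days`, `window_days`, `n`.
#' @export
periodogram <- function(series, step_days = NULL,
                        taper = c("rectangular", "hann")) {
  taper <- match.arg(taper)
  if (inherits(series, "feature_series")) {
    if (series$rejected) stopf("series window was rejected (too much missing data)")
    step_days <- series$step_days
    series <- series$values
  }
  if (is.null(step_days)) stopf("'step_days' is required for a plain vector")
  if (anyNA(series)) stopf("series contains missing entries; interpolate upstream")
  n <- length(series)
  if (n < 8) stopf("series too short (length %d < 8)", n)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    series <- series * w / sqrt(mean(w^2))
  }
  ft <- fft(series)
  nf <- floor(n / 2)
  structure(list(frequency = (1:nf) / (n * step_days),
                 power = Mod(ft[2:(nf + 1)])^2 / n,
                 step_days = step_days, window_days = n * step_days, n = n),
            class = "gps_spectrum")
}

#' @export
print.gps_spectrum <- function(x, ...) {
  cat(sprintf("<gps_spectrum> %d bins, step %.4g d, window %.4g d, peak %.4g @ %.4g c/d\n",
              length(x$power), x$step_days, x$window_days,
              max(x$power), x$frequency[which.max(x$power)]))
  invisible(x)
}

#' Top-k ranked spectral peaks
#'
#' Returns the `k` strongest peaks of a spectrum, rank 1 = maximum power,
#' period = reciprocal frequency. Candidate periods are restricted to
#' `[2 * step, window / 2]` (resolvable and at least twice sampled). By
#' default a peak must be a local maximum of the power spectrum, so the
#' leakage shoulders flanking a dominant bin are not reported as distinct
#' periodic components; set `local_only = FALSE` for the raw k highest bins.
#' Exact power ties go to the lower frequency (longer period).
#'
#' @param spectrum a [periodogram()] result.
#' @param k number of peaks (default 5); fewer are returned when fewer
#'   candidates exist.
#' @param local_only require peaks to be local maxima (default TRUE).
#' @return data.frame `rank`, `period_days`, `frequency`, `power` with powers
#'   nonincreasing in rank.
#' @export
top_k_peaks <- function(spectrum, k = 5, local_only = TRUE) {
  p <- spectrum$power
  f <- spectrum$frequency
  period <- 1 / f
  cand <- period >= 2 * spectrum$step_days & period <= spectrum$window_days / 2
  if (local_only && length(p) > 1) {
    left <- c(-Inf, p[-length(p)])
    right <- c(p[-1], -Inf)
    cand <- cand & p >= left & p >= right & (p > left | p > right)
  }
  idx <- which(cand)
  if (!length(idx))
    return(data.frame(rank = integer(), period_days = numeric(),
                      frequency = numeric(), power = numeric()))
  ord <- idx[order(-p[idx], f[idx])]
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(rank = seq_along(ord), period_days = period[ord],
             frequency = f[ord], power = p[ord])
}

#' Ranked spectral summary for one participant-feature-window
#'
#' Builds the regular series, transforms it, and returns the five ranked
#' (power, frequency, period) peaks that feed the group tests (maximum power
#' is the headline "Fourier spectrum power") - or NULL when the window is
#' rejected for missingness.
#'
#' @param time_days,values observations passed to [build_feature_series()].
#' @param window_days window length in days (default 28).
#' @param granularity `"hourly"` (default) or `"daily"`.
#' @param k number of ranked peaks.
#' @param ... further arguments to [build_feature_series()].
#' @return data.frame as [top_k_peaks()], or NULL for a rejected window.
#' @export
window_spectral_summary <- function(time_days, values, window_days = 28,
                                    granularity = "hourly", k = 5, ...) {
  fs <- build_feature_series(time_days, values, window_days,
                             granularity = granularity, ...)
  if (fs$rejected) return(NULL)
  top_k_peaks(periodogram(fs), k = k)
}

#' Consensus periods across a group's ranked peaks
#'
#' Tallies, per integer-day period, how many of a group's participants carry
#' that period among their top-k peaks, together with the summed rank score
#' (lower = stronger). A peak is attributed to the integer day `d =
#' round(period)` only when `d >= 1` and the period lies within `tol * d` of
#' it; sub-day and far-off-grid peaks are left out of the integer-day
#' consensus. The majority flag marks periods carried by strictly more than
#' half of the group.
#'
#' @param peak_sets named list (one element per participant) of
#'   [top_k_peaks()] data.frames.
#' @param group_size number of participants in the group; defaults to
#'   `length(peak_sets)`.
#' @param tol relative tolerance for snapping a period to its integer day.
#' @return data.frame `period_days`, `n_participants`, `rank_sum`,
#'   `majority`, sorted by period.
#' @export
cohort_period_consensus <- function(peak_sets, group_size = length(peak_sets),
                                    tol = 0.25) {
  rows <- list()
  for (pid in names(peak_sets) %||% seq_along(peak_sets)) {
    ps <- peak_sets[[pid]]
    if (is.null(ps) || !nrow(ps)) next
    d <- round(ps$period_days)
    ok <- d >= 1 & abs(ps$period_days - d) <= tol * d
    if (!any(ok)) next
    # one vote per participant per period: keep the best (lowest) rank
    best <- tapply(ps$rank[ok], d[ok], min)
    rows[[length(rows) + 1]] <- data.frame(pid = pid,
                                           period_days = as.numeric(names(best)),
                                           rank = as.numeric(best))
  }
  if (!length(rows))
    return(data.frame(period_days = numeric(), n_participants = integer(),
                      rank_sum = numeric(), majority = logical()))
  all <- do.call(rbind, rows)
  agg <- aggregate(cbind(n_participants = pid, rank_sum = rank) ~ period_days,
                   data = transform(all, pid = 1), FUN = sum)
  agg$n_participants <- as.integer(agg$n_participants)
  agg$majority <- agg$n_participants > group_size / 2
  agg[order(agg$period_days), ]
}
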