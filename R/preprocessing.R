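#' Drop fixes whose reported GPS accuracy is too poor
#'
#' @param fixes time-sorted data.frame with an `accuracy` column (meters).
#' @param max_error_m retention threshold: fixes with `accuracy <=
#'   max_error_m` are kept (default 50 m).
#' @return the retained fixes, order preserved.
#' @export
filter_accuracy <- function(fixes, max_error_m = 50) {
  fixes[fixes$accuracy <= max_error_m, , drop = FALSE]
}

#' Average projected positions into a regular 10-second grid
#'
#' Each grid bin holds the mean position of the fixes falling in it; bins
#' containing no fix (no data for over 10 s) are marked invalid and carry NA
#' coordinates. The grid is anchored at `day_start` (local midnight) and by
#' default spans one full day (8640 bins).
#'
#' @param points data.frame with `t` (seconds), `x`, `y` (meters; already
#'   projected, see [project_to_meters()]).
#' @param day_start grid anchor in the same time scale as `t`; defaults to
#'   the midnight at or before the first point.
#' @param n_bins number of 10-s bins in the grid (default 8640 = 24 h).
#' @param bin_s bin width in seconds (default 10).
#' @return data.frame `bin_start`, `x`, `y`, `n` (fix count), `valid`.
#' @export
bin_10s <- function(points, day_start = NULL, n_bins = 8640, bin_s = 10) {
  if (is.null(day_start))
    day_start <- if (nrow(points)) floor(min(points$t) / 86400) * 86400 else 0
  idx <- floor((points$t - day_start) / bin_s) + 1
  inside <- idx >= 1 & idx <= n_bins
  idx <- idx[inside]
  out <- data.frame(bin_start = day_start + (seq_len(n_bins) - 1) * bin_s,
                    x = NA_real_, y = NA_real_, n = 0L, valid = FALSE)
  if (length(idx)) {
    n <- tabulate(idx, nbins = n_bins)
    sx <- rep(0, n_bins); sy <- rep(0, n_bins)
    sx[seq_len(n_bins)] <- unname(rowsum_safe(points$x[inside], idx, n_bins))
    sy[seq_len(n_bins)] <- unname(rowsum_safe(points$y[inside], idx, n_bins))
    out$n <- n
    out$x <- ifelse(n > 0, sx / pmax(n, 1), NA_real_)
    out$y <- ifelse(n > 0, sy / pmax(n, 1), NA_real_)
    out$valid <- n > 0
  }
  out
}

# Sum `v` by integer group `g` into a dense length-`n` vector.
rowsum_safe <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Segment a binned trajectory into stationary / moving / unknown states
#'
#' Consecutive valid 10-s bins displaced by more than `sqrt(10)` m are a
#' moving step, otherwise stationary. Steps touching an invalid bin are
#' unknown; each maximal unknown run flanked by valid bins is resolved to
#' moving when the displacement across it, prorated to any 6-minute span
#' (linear motion assumption), reaches 75 m or more - else stationary.
#' Unknown runs at the edges of the record stay unknown.
#'
#' @param bins output of [bin_10s()].
#' @param move_dist_m per-10-s displacement above which a step is movement.
#' @param unknown_dist_m displacement threshold resolving unknown runs.
#' @param unknown_window_s window (seconds) over which `unknown_dist_m`
#'   applies.
#' @return data.frame of segments: `start`, `end` (seconds), `state`,
#'   `cx`, `cy` (centroid of valid bins, stationary segments only). Segments
#'   partition the observed bin span.
#' @export
classify_states <- function(bins, move_dist_m = sqrt(10),
                            unknown_dist_m = 75, unknown_window_s = 360) {
  n <- nrow(bins)
  if (n < 2) stopf("need at least 2 bins to classify states")
  bin_s <- bins$bin_start[2] - bins$bin_start[1]
  v <- bins$valid
  dx <- diff(bins$x); dy <- diff(bins$y)
  d <- sqrt(dx^2 + dy^2)
  both <- v[-n] & v[-1]
  state <- ifelse(both, ifelse(d > move_dist_m, "moving", "stationary"), "unknown")
  # resolve interior unknown runs via the windowed displacement rule
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in which(r$values == "unknown")) {
    i0 <- starts[j]; i1 <- ends[j]
    if (v[i0] && v[i1 + 1]) {
      span <- (i1 + 1 - i0) * bin_s
      disp <- sqrt((bins$x[i1 + 1] - bins$x[i0])^2 + (bins$y[i1 + 1] - bins$y[i0])^2)
      eff <- disp * min(1, unknown_window_s / span)
      state[i0:i1] <- if (eff >= unknown_dist_m) "moving" else "stationary"
    }
  }
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  seg <- data.frame(
    start = bins$bin_start[starts],
    end = bins$bin_start[ends] + bin_s,
    state = r$values, cx = NA_real_, cy = NA_real_,
    stringsAsFactors = FALSE)
  # the final bin's own dwell belongs to the last segment
  seg$end[nrow(seg)] <- seg$end[nrow(seg)] + bin_s
  seg_idx <- findInterval(bins$bin_start, seg$start)
  sel <- v & seg_idx >= 1
  if (any(sel)) {
    k <- nrow(seg)
    cnt <- rowsum_safe(rep(1, sum(sel)), seg_idx[sel], k)
    cx <- rowsum_safe(bins$x[sel], seg_idx[sel], k) / pmax(cnt, 1)
    cy <- rowsum_safe(bins$y[sel], seg_idx[sel], k) / pmax(cnt, 1)
    stat <- seg$state == "stationary" & cnt > 0
    seg$cx[stat] <- cx[stat]; seg$cy[stat] <- cy[stat]
  }
  seg
}

#' Multiple stochastic completions of a gappy binned trajectory
#'
#' Interior invalid runs no longer than `max_gap_min` are filled by linear
#' interpolation between the flanking valid bins plus zero-mean Gaussian
#' jitter, independently for each of `n_sim` completions. The jitter is a
#' smooth stochastic bridge: one Gaussian displacement per gap per
#' completion, scaled by a sine profile that vanishes at the flanking valid
#' bins, so a completion is a plausible continuous excursion rather than
#' point-wise noise, and the across-completion mean of any filled bin is its
#' linear interpolant. Longer runs and leading/trailing gaps are filled from
#' a donor day (same clock bins) when one is supplied, else left invalid.
#' Valid bins are never altered.
#'
#' @param bins output of [bin_10s()] for one day.
#' @param n_sim number of stochastic completions (default 10).
#' @param jitter_sd jitter standard deviation in meters.
#' @param max_gap_min longest interior gap (minutes) filled by interpolation.
#' @param donor optional bins data.frame on the same grid (another day of the
#'   same participant) used to fill long/edge gaps.
#' @param seed optional RNG seed.
#' @return a list of `n_sim` bins data.frames.
#' @export
impute_gaps <- function(bins, n_sim = 10, jitter_sd = 5, max_gap_min = 60,
                        donor = NULL, seed = NULL) {
  v <- which(bins$valid)
  if (length(v) < 2) stopf("uninterpolatable day: fewer than 2 valid bins")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(bins)
  bin_s <- bins$bin_start[2] - bins$bin_start[1]
  max_run <- max_gap_min * 60 / bin_s
  gaps <- list()
  fill_donor <- integer(0)
  r <- rle(bins$valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in which(!r$values)) {
    run <- starts[j]:ends[j]
    interior <- starts[j] > min(v) && ends[j] < max(v)
    if (interior && length(run) <= max_run) gaps[[length(gaps) + 1]] <- run
    else fill_donor <- c(fill_donor, run)
  }
  fill_interp <- unlist(gaps)
  base <- bins
  if (length(fill_interp)) {
    base$x[fill_interp] <- approx(v, bins$x[v], xout = fill_interp)$y
    base$y[fill_interp] <- approx(v, bins$y[v], xout = fill_interp)$y
    base$valid[fill_interp] <- TRUE
  }
  if (length(fill_donor) && !is.null(donor)) {
    ok <- fill_donor[donor$valid[fill_donor]]
    base$x[ok] <- donor$x[ok]; base$y[ok] <- donor$y[ok]
    base$valid[ok] <- TRUE
  }
  lapply(seq_len(n_sim), function(s) {
    out <- base
    if (jitter_sd > 0) {
      for (run in gaps) {
        w <- sin(pi * seq_along(run) / (length(run) + 1))
        out$x[run] <- out$x[run] + rnorm(1, 0, jitter_sd) * w
        out$y[run] <- out$y[run] + rnorm(1, 0, jitter_sd) * w
      }
    }
    out
  })
}

#' Day-level data validity
#'
#' A clock hour is valid when it contains at least one valid 10-s bin; a day
#' enters the analysis when at least `threshold_hours` hours are valid (one
#' quarter of the day by default).
#'
#' @param bins output of [bin_10s()] covering one local calendar day.
#' @param threshold_hours inclusion threshold (default 6).
#' @param participant,date optional identifiers carried through.
#' @return data.frame `participant_id`, `date`, `valid_hours`, `included`.
#' @export
day_validity <- function(bins, threshold_hours = 6, participant = NA, date = NA) {
  hour <- floor((bins$bin_start - bins$bin_start[1]) / 3600)
  vh <- length(unique(hour[bins$valid]))
  data.frame(participant_id = participant, date = date,
             valid_hours = vh, included = vh >= threshold_hours,
             stringsAsFactors = FALSE)
}

#' Resolve the daily EMA score per mood item
#'
#' The primary (12:45) prompt takes precedence; when it is missing the 17:00
#' fallback is used; when both are missing the item is NA.
#'
#' @param prompts long-format rows for one participant-day with columns
#'   `prompt` (`"primary"`/`"fallback"`), `item`, `score`.
#' @return named integer vector over items `dep`, `mania`, `fatigue`,
#'   `irrit` (NA when unscored).
#' @export
resolve_daily_ema <- function(prompts) {
  sc <- prompts$score
  if (any(!is.na(sc) & (sc < 1 | sc > 5 | sc != round(sc))))
    stopf("EMA scores must be integers in 1..5")
  items <- c("dep", "mania", "fatigue", "irrit")
  out <- setNames(rep(NA_integer_, length(items)), items)
  for (it in items) {
    rows <- prompts[prompts$item == it & !is.na(prompts$score), , drop = FALSE]
    if (!nrow(rows)) next
    prim <- rows$score[rows$prompt == "primary"]
    fall <- rows$score[rows$prompt == "fallback"]
    out[[it]] <- if (length(prim)) as.integer(prim[1]) else
      if (length(fall)) as.integer(fall[1]) else NA_integer_
  }
  out
}
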