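#' Project geographic coordinates to local meters
#'
#' Equirectangular projection around a fixed per-participant reference point:
#' `y = (lat - ref_lat) * 111320`, `x = (lon - ref_lon) * 111320 *
#' cos(ref_lat)`. Adequate at the within-city scale of daily mobility.
#'
#' @param lat,lon coordinates in degrees (vectors).
#' @param ref_lat,ref_lon reference point in degrees.
#' @return data.frame `x`, `y` in meters east/north of the reference.
#' @export
project_to_meters <- function(lat, lon, ref_lat, ref_lon) {
  if (any(abs(lat) > 90, na.rm = TRUE) || abs(ref_lat) > 90)
    stopf("latitude out of range [-90, 90]")
  if (any(abs(lon) > 180, na.rm = TRUE) || abs(ref_lon) > 180)
    stopf("longitude out of range [-180, 180]")
  data.frame(x = (lon - ref_lon) * 111320 * cos(ref_lat * pi / 180),
             y = (lat - ref_lat) * 111320)
}

# Inverse of project_to_meters (generator-side).
unproject_from_meters <- function(x, y, ref_lat, ref_lon) {
  data.frame(lat = ref_lat + y / 111320,
             lon = ref_lon + x / (111320 * cos(ref_lat * pi / 180)))
}

#' Greedy location clustering of stationary bins
#'
#' Significant-place detection: each stationary bin joins the nearest
#' existing cluster centroid within `radius_m`, else opens a new cluster;
#' centroids are running dwell-weighted means. The home cluster is the one
#' with maximal dwell between 00:00 and 06:00 local time (falling back to
#' maximal total dwell when that window is empty).
#'
#' @param x,y stationary bin coordinates (meters).
#' @param t bin start times (seconds) on the same scale as `day_start`.
#' @param day_start local midnight (seconds); used only for the home window.
#' @param radius_m cluster radius (default 500 m).
#' @param dwell_s dwell credited per bin (default 10 s).
#' @return data.frame `cluster`, `cx`, `cy`, `dwell_s`, `is_home`, plus the
#'   per-bin assignment as attribute `"assign"`. Zero rows if no input.
#' @export
cluster_locations <- function(x, y, t = NULL, day_start = 0, radius_m = 500,
                              dwell_s = 10) {
  if (length(x) == 0)
    return(data.frame(cluster = integer(), cx = numeric(), cy = numeric(),
                      dwell_s = numeric(), is_home = logical()))
  res <- greedy_cluster(as.numeric(x), as.numeric(y),
                        rep(dwell_s, length(x))[seq_along(x)], radius_m)
  k <- length(res$cx)
  out <- data.frame(cluster = seq_len(k), cx = res$cx, cy = res$cy,
                    dwell_s = res$dwell, is_home = FALSE)
  if (!is.null(t)) {
    night <- (t - day_start) >= 0 & (t - day_start) < 6 * 3600
    nd <- rowsum_safe(rep(dwell_s, length(x))[seq_along(x)] * night, res$assign, k)
    home <- if (any(nd > 0)) which.max(nd) else which.max(out$dwell_s)
  } else home <- which.max(out$dwell_s)
  out$is_home[home] <- TRUE
  attr(out, "assign") <- res$assign
  out
}

#' Location variance of a day's stationary positions
#'
#' `LV = ln(var(x) + var(y) + eps)` with population variances and a floor of
#' `eps = 1e-6` m^2 so a perfectly still day is finite.
#'
#' @param x,y stationary positions (meters).
#' @param eps variance floor (m^2).
#' @return LV in log m^2.
#' @export
location_variance <- function(x, y, eps = 1e-6) {
  if (length(x) == 0) stopf("no stationary positions")
  pvar <- function(v) mean((v - mean(v))^2)
  log(pvar(x) + pvar(y) + eps)
}

#' Shannon entropy of the dwell-time distribution over clusters
#'
#' `-sum(p_i * log(p_i))` in nats with `p_i` the dwell share of cluster `i`;
#' zero-dwell clusters contribute nothing.
#'
#' @param dwell nonnegative dwell durations, positive total.
#' @return entropy in nats, in `[0, log(length(dwell))]`.
#' @export
location_entropy <- function(dwell) {
  if (any(dwell < 0)) stopf("dwell durations must be >= 0")
  tot <- sum(dwell)
  if (tot <= 0) stopf("total dwell must be > 0")
  p <- dwell[dwell > 0] / tot
  -sum(p * log(p))
}

# Map each bin to its segment state ("stationary"/"moving"/"unknown").
bin_states <- function(bins, segments) {
  idx <- findInterval(bins$bin_start, segments$start)
  out <- rep(NA_character_, nrow(bins))
  inside <- idx >= 1 & bins$bin_start < segments$end[nrow(segments)]
  out[inside] <- segments$state[idx[inside]]
  out
}

#' Compute the eight mobility features for one completed participant-day
#'
#' Stationary-state features: location variance (LV), number of clusters
#' (NC), entropy, homestay (dwell fraction at the home cluster). Moving-state
#' feature: transition time (TT = moving / (stationary + moving) seconds).
#' State-free features: total distance (TD, sum of consecutive-valid-bin
#' displacements), speed mean (SM) and population speed variance (SV) over
#' the per-step displacement / 10 s.
#'
#' @param segments output of [classify_states()].
#' @param bins the completed (imputed) bins the segments were computed from.
#' @param clusters output of [cluster_locations()] on the stationary bins.
#' @param states optional precomputed per-bin states (from `bin_states`).
#' @return one-row data.frame `lv`, `sm`, `sv`, `nc`, `entropy`, `homestay`,
#'   `tt`, `td`.
#' @export
compute_day_features <- function(segments, bins, clusters, states = NULL) {
  st <- states %||% bin_states(bins, segments)
  stat_sel <- bins$valid & st == "stationary" & !is.na(st)
  dur <- function(s) sum(segments$end[segments$state == s] -
                           segments$start[segments$state == s])
  mov_s <- dur("moving"); sta_s <- dur("stationary")
  tt <- if (mov_s + sta_s > 0) mov_s / (mov_s + sta_s) else 0
  v <- which(bins$valid)
  td <- 0; sm <- 0; sv <- 0
  if (length(v) >= 2) {
    pairs <- v[-length(v)][diff(v) == 1]
    if (length(pairs)) {
      d <- sqrt((bins$x[pairs + 1] - bins$x[pairs])^2 +
                  (bins$y[pairs + 1] - bins$y[pairs])^2)
      td <- sum(d)
      spd <- d / (bins$bin_start[2] - bins$bin_start[1])
      sm <- mean(spd); sv <- mean((spd - sm)^2)
    }
  }
  if (any(stat_sel) && nrow(clusters)) {
    lv <- location_variance(bins$x[stat_sel], bins$y[stat_sel])
    nc <- nrow(clusters)
    ent <- location_entropy(clusters$dwell_s)
    homestay <- clusters$dwell_s[clusters$is_home][1] / sum(clusters$dwell_s)
  } else {
    lv <- NA_real_; nc <- 0L; ent <- NA_real_; homestay <- NA_real_
  }
  data.frame(lv = lv, sm = sm, sv = sv, nc = nc, entropy = ent,
             homestay = homestay, tt = tt, td = td)
}

#' Preprocess and featurize one participant-day of raw fixes
#'
#' Runs the full per-day chain: accuracy filter, projection, 10-s binning,
#' validity check, `n_sim` stochastic gap completions, state classification,
#' location clustering, and feature computation - returning the features
#' averaged across the completions.
#'
#' @param fixes raw fixes data.frame (`t`, `lat`, `lon`, `accuracy`).
#' @param ref_lat,ref_lon participant projection reference (degrees).
#' @param day_start local-midnight anchor in the `t` time scale.
#' @param max_error_m accuracy threshold (m).
#' @param n_sim number of imputed completions averaged over.
#' @param jitter_sd imputation jitter sd (m); defaults to the GPS noise scale.
#' @param min_valid_hours day inclusion threshold.
#' @param cluster_radius_m location cluster radius (m).
#' @param donor optional donor-day bins for long-gap filling.
#' @param seed RNG seed for the imputation jitter.
#' @param hourly also compute per-hour LV/entropy series (for spectral input).
#' @return a list: `features` (one-row data.frame incl. `valid_hours`,
#'   `included`, `n_imputations`), `validity`, and when `hourly=TRUE` an
#'   `hourly` data.frame (`hour`, `lv`, `entropy`). Features are NA for
#'   excluded days.
#' @export
process_day <- function(fixes, ref_lat, ref_lon, day_start,
                        max_error_m = 50, n_sim = 10, jitter_sd = 5,
                        min_valid_hours = 6, cluster_radius_m = 500,
                        donor = NULL, seed = NULL, hourly = FALSE) {
  na_row <- data.frame(lv = NA_real_, sm = NA_real_, sv = NA_real_,
                       nc = NA_real_, entropy = NA_real_, homestay = NA_real_,
                       tt = NA_real_, td = NA_real_)
  fixes <- filter_accuracy(fixes, max_error_m)
  if (nrow(fixes) == 0) {
    val <- data.frame(participant_id = NA, date = NA, valid_hours = 0L,
                      included = FALSE)
    return(list(features = cbind(na_row, val[3:4], n_imputations = 0L),
                validity = val, hourly = NULL))
  }
  pr <- project_to_meters(fixes$lat, fixes$lon, ref_lat, ref_lon)
  pts <- data.frame(t = fixes$t, x = pr$x, y = pr$y)
  bins <- bin_10s(pts, day_start = day_start)
  val <- day_validity(bins, threshold_hours = min_valid_hours)
  if (!val$included)
    return(list(features = cbind(na_row, val[3:4], n_imputations = 0L),
                validity = val, hourly = NULL))
  # States are classified once, on the observed bins: duty-cycle gaps are
  # resolved by the windowed 75 m rule, not corrupted by imputation jitter.
  # The stochastic completions then supply positions for the
  # position-dependent features (LV, clusters, entropy, homestay, TD, SM,
  # SV), whose values are averaged across completions.
  seg <- classify_states(bins)
  stt <- bin_states(bins, seg)
  sims <- impute_gaps(bins, n_sim = n_sim, jitter_sd = jitter_sd,
                      donor = donor, seed = seed)
  feats <- vector("list", length(sims))
  hr <- NULL
  for (s in seq_along(sims)) {
    b <- sims[[s]]
    sel <- b$valid & stt == "stationary" & !is.na(stt)
    cl <- cluster_locations(b$x[sel], b$y[sel], t = b$bin_start[sel],
                            day_start = day_start, radius_m = cluster_radius_m)
    feats[[s]] <- compute_day_features(seg, b, cl, states = stt)
    if (hourly) {
      h <- hourly_features(b, stt, day_start)
      hr <- if (is.null(hr)) h else
        data.frame(hour = h$hour, lv = hr$lv + h$lv, entropy = hr$entropy + h$entropy)
    }
  }
  fmat <- do.call(rbind, feats)
  avg <- as.data.frame(as.list(colMeans(fmat, na.rm = TRUE)))
  if (hourly && !is.null(hr)) { hr$lv <- hr$lv / length(sims); hr$entropy <- hr$entropy / length(sims) }
  list(features = cbind(avg, val[3:4], n_imputations = length(sims)),
       validity = val, hourly = hr)
}

# Per-hour LV and dwell entropy from a completed day (spectral input).
# Entropy per hour is over a 100 m within-hour position grid - a cheap
# stand-in for per-hour cluster dwell that preserves the diversity signal.
hourly_features <- function(bins, states, day_start) {
  hour <- floor((bins$bin_start - day_start) / 3600)
  sel <- bins$valid & states == "stationary" & !is.na(states)
  lv <- rep(NA_real_, 24); ent <- rep(NA_real_, 24)
  for (h in 0:23) {
    i <- sel & hour == h
    if (sum(i) >= 2) {
      lv[h + 1] <- location_variance(bins$x[i], bins$y[i])
      cell <- paste(round(bins$x[i] / 100), round(bins$y[i] / 100))
      ent[h + 1] <- location_entropy(as.numeric(table(cell)) * 10)
    }
  }
  data.frame(hour = 0:23, lv = lv, entropy = ent)
}

#' Regularize a feature series for spectral analysis
#'
#' Places the values on a fixed daily or hourly grid over the requested
#' window, linearly interpolates missing entries, flags the window as
#' rejected when more than `max_missing` of its grid points were missing,
#' and removes the mean.
#'
#' @param time_days observation times in days since follow-up start (day 1 =
#'   0; hourly values at `day + hour/24`).
#' @param values feature values at `time_days`.
#' @param window_days window length in days.
#' @param start_day window start (days, default 0).
#' @param granularity `"hourly"` or `"daily"`.
#' @param max_missing rejection threshold on the missing fraction.
#' @return an object of class `feature_series`: list with `values` (demeaned,
#'   gap-free), `step_days`, `window_days`, `missing_frac`, `rejected`.
#' @export
build_feature_series <- function(time_days, values, window_days,
                                 start_day = 0,
                                 granularity = c("hourly", "daily"),
                                 max_missing = 0.25) {
  granularity <- match.arg(granularity)
  step <- if (granularity == "hourly") 1 / 24 else 1
  grid <- seq(start_day, by = step, length.out = round(window_days / step))
  ok <- !is.na(values)
  idx <- round((time_days[ok] - start_day) / step) + 1
  z <- rep(NA_real_, length(grid))
  inside <- idx >= 1 & idx <= length(grid)
  z[idx[inside]] <- values[ok][inside]
  missing_frac <- mean(is.na(z))
  rejected <- missing_frac > max_missing || sum(!is.na(z)) < 2
  if (!rejected) {
    z <- approx(grid[!is.na(z)], z[!is.na(z)], xout = grid, rule = 2)$y
    z <- z - mean(z)
  }
  structure(list(values = if (rejected) NULL else z, step_days = step,
                 window_days = window_days, missing_frac = missing_frac,
                 rejected = rejected),
            class = "feature_series")
}
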