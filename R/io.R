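#' Write / read Beiwe-style GPS CSV files
#'
#' The on-disk dialect is one row per fix with header
#' `timestamp,UTC_time,latitude,longitude,altitude,accuracy`: `timestamp` is
#' UTC seconds (3 decimals), coordinates carry 8 decimals and accuracy 3, so
#' files round-trip losslessly at that precision.
#'
#' @param fixes data.frame with columns `t`, `lat`, `lon`, `altitude`
#'   (optional), `accuracy`.
#' @param path file path.
#' @return `write_beiwe_csv` returns `path` invisibly; `read_beiwe_csv`
#'   returns a time-sorted data.frame `t`, `lat`, `lon`, `altitude`,
#'   `accuracy`.
#' @export
write_beiwe_csv <- function(fixes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("timestamp,UTC_time,latitude,longitude,altitude,accuracy", con)
  if (nrow(fixes)) {
    utc <- format(as.POSIXct(fixes$t, origin = "1970-01-01", tz = "UTC"),
                  "%Y-%m-%dT%H:%M:%S")
    alt <- if (is.null(fixes$altitude)) rep(0, nrow(fixes)) else fixes$altitude
    writeLines(sprintf("%.3f,%s,%.8f,%.8f,%.1f,%.3f",
                       fixes$t, utc, fixes$lat, fixes$lon, alt, fixes$accuracy), con)
  }
  invisible(path)
}

#' @rdname write_beiwe_csv
#' @export
read_beiwe_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "latitude", "longitude", "accuracy")
  if (!all(need %in% names(df)))
    stopf("not a Beiwe-style GPS CSV: missing column(s) %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(t = as.numeric(df$timestamp), lat = df$latitude,
                    lon = df$longitude,
                    altitude = if ("altitude" %in% names(df)) df$altitude else 0,
                    accuracy = df$accuracy)
  out[order(out$t), , drop = FALSE]
}

#' Write / read the long-format EMA CSV
#'
#' One row per participant-day-item with columns
#' `participant_id,date,prompt,item,score`.
#'
#' @param moods data.frame from [simulate_mood_series()] (possibly row-bound
#'   over participants).
#' @param path file path.
#' @return `write_ema_csv` returns `path` invisibly; `read_ema_csv` the long
#'   data.frame.
#' @export
write_ema_csv <- function(moods, path) {
  items <- c(dep = "ema_dep", mania = "ema_mania",
             fatigue = "ema_fatigue", irrit = "ema_irrit")
  rows <- lapply(names(items), function(it) {
    data.frame(participant_id = moods$participant_id,
               date = as.character(moods$date),
               prompt = ifelse(is.na(moods$prompt), "", moods$prompt),
               item = it, score = moods[[items[[it]]]],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  long <- long[order(long$participant_id, long$date, long$item), ]
  write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ema_csv
#' @export
read_ema_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$score <- suppressWarnings(as.integer(df$score))
  df
}

# Pivot the long EMA table back to one row per participant-day with the
# primary/fallback precedence applied per item.
ema_daily_table <- function(ema_long) {
  key <- interaction(ema_long$participant_id, ema_long$date, drop = TRUE)
  rows <- lapply(split(ema_long, key), function(d) {
    sc <- resolve_daily_ema(d)
    data.frame(participant_id = d$participant_id[1], date = d$date[1],
               ema_dep = sc[["dep"]], ema_mania = sc[["mania"]],
               ema_fatigue = sc[["fatigue"]], ema_irrit = sc[["irrit"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$date), ]
}

#' Simulate a full cohort to disk
#'
#' Writes the cohort manifest (`cohort.csv`), the EMA table (`ema.csv`), and
#' one Beiwe-style GPS CSV per participant-day under `gps/<id>/<date>.csv`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the cohort data.frame and the written paths.
#' @export
simulate_cohort <- function(config, out_dir) {
  dir.create(file.path(out_dir, "gps"), recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  moods_all <- vector("list", nrow(cohort))
  gps_paths <- character()
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    moods <- simulate_mood_series(p, config)
    moods_all[[i]] <- moods
    pdir <- file.path(out_dir, "gps", p$id)
    dir.create(pdir, showWarnings = FALSE)
    for (d in seq_len(nrow(moods))) {
      fixes <- simulate_day_trajectory(p, moods[d, ], config)
      if (nrow(fixes) == 0) next
      fp <- file.path(pdir, paste0(moods$date[d], ".csv"))
      write_beiwe_csv(fixes, fp)
      gps_paths <- c(gps_paths, fp)
    }
  }
  moods <- do.call(rbind, moods_all)
  if (!is.null(moods)) write_ema_csv(moods, file.path(out_dir, "ema.csv"))
  invisible(list(cohort = cohort, moods = moods,
                 paths = list(cohort = file.path(out_dir, "cohort.csv"),
                              ema = file.path(out_dir, "ema.csv"),
                              gps = gps_paths)))
}
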