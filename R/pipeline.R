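#' Default pipeline configuration
#'
#' Nested list of every stage's parameters at its module default; the YAML
#' config file loaded by [load_config()] may override any subset.
#'
#' @return a named list with sections `seed`, `out_dir`, `stages`, `cohort`,
#'   `preprocess`, `features`, `spectral`, `analyze`.
#' @export
default_config <- function() {
  cc <- unclass(cohort_config())
  cc$start_date <- as.character(cc$start_date)
  cc$mood_effect <- as.list(cc$mood_effect)
  list(
    seed = 1L,
    out_dir = "gpsrhythms-out",
    stages = list(simulate = TRUE, preprocess = TRUE, features = TRUE,
                  spectral = TRUE, analyze = TRUE),
    cohort = cc,
    preprocess = list(max_error_m = 50, min_valid_hours = 6,
                      n_imputations = 10, max_gap_min = 60, jitter_sd = NA),
    features = list(cluster_radius_m = 500),
    spectral = list(window_days = 28, granularity = "hourly", k = 5,
                    consensus_tol = 0.25, taper = "rectangular"),
    analyze = list(vif_threshold = 3, cluster_robust = FALSE))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys (naming the offending key), fills
#' every unset parameter with its module default, and validates the cohort
#' section through [cohort_config()]. An empty file yields the defaults.
#'
#' @param path YAML file path.
#' @return a validated configuration list (see [default_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  user <- yaml::read_yaml(path) %||% list()
  defs <- default_config()
  bad <- setdiff(names(user), names(defs))
  if (length(bad)) stopf("unknown config key '%s'", bad[1])
  for (sec in names(user)) {
    if (is.list(defs[[sec]]) && is.list(user[[sec]])) {
      bad <- setdiff(names(user[[sec]]), names(defs[[sec]]))
      if (length(bad)) stopf("unknown config key '%s.%s'", sec, bad[1])
    }
  }
  cfg <- modifyList(defs, user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cc <- cfg$cohort
  cc$mood_effect <- unlist(cc$mood_effect)
  do.call(cohort_config, c(cc[setdiff(names(cc), "seed")], list(seed = cfg$seed)))
  cfg$cohort$seed <- cfg$seed
  cfg
}

as_cohort_config <- function(cfg) {
  cc <- cfg$cohort
  cc$mood_effect <- unlist(cc$mood_effect)
  do.call(cohort_config, cc)
}

config_hash <- function(cfg, sections) {
  fnv1a(paste(deparse(cfg[c("seed", sections)]), collapse = ""))
}

stage_fresh <- function(out_dir, stage, hash, outputs) {
  hf <- file.path(out_dir, paste0(".stage_", stage))
  all(file.exists(file.path(out_dir, outputs))) && file.exists(hf) &&
    readLines(hf, warn = FALSE)[1] == hash
}

stage_stamp <- function(out_dir, stage, hash) {
  writeLines(hash, file.path(out_dir, paste0(".stage_", stage)))
}

#' Run the simulate / preprocess / features / spectral / analyze pipeline
#'
#' Executes the enabled stages in dependency order against a plain directory
#' artifact store. Every stage output is stamped with a hash of the config
#' sections it depends on (plus the seed), and an up-to-date stage is skipped
#' on re-runs. A JSON manifest of produced artifacts is written at the end.
#'
#' @param config a configuration list ([default_config()] /
#'   [load_config()]) or a path to a YAML config.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @param force rerun stages even when up to date.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         force = FALSE) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  ran <- character()

  h_sim <- config_hash(config, "cohort")
  if (isTRUE(st$simulate)) {
    if (force || !stage_fresh(out_dir, "simulate", h_sim,
                              c("cohort.csv", "ema.csv"))) {
      simulate_cohort(as_cohort_config(config), out_dir)
      stage_stamp(out_dir, "simulate", h_sim)
      ran <- c(ran, "simulate")
    }
  }

  h_feat <- paste0(h_sim, config_hash(config, c("preprocess", "features")))
  feat_out <- c("features.csv", "features_hourly.csv", "segments.csv",
                "validity.csv")
  if (isTRUE(st$preprocess) || isTRUE(st$features)) {
    if (!file.exists(file.path(out_dir, "cohort.csv")))
      stopf("stage 'features' is missing upstream artifact 'cohort.csv' (run simulate)")
    if (force || !stage_fresh(out_dir, "features", h_feat, feat_out)) {
      stage_features(config, out_dir)
      stage_stamp(out_dir, "features", h_feat)
      ran <- c(ran, "features")
    }
  }

  h_spec <- paste0(h_feat, config_hash(config, "spectral"))
  if (isTRUE(st$spectral)) {
    if (!file.exists(file.path(out_dir, "features_hourly.csv")))
      stopf("stage 'spectral' is missing upstream artifact 'features_hourly.csv'")
    if (force || !stage_fresh(out_dir, "spectral", h_spec,
                              c("spectra.csv", "consensus.csv"))) {
      stage_spectral(config, out_dir)
      stage_stamp(out_dir, "spectral", h_spec)
      ran <- c(ran, "spectral")
    }
  }

  h_an <- paste0(h_spec, config_hash(config, "analyze"))
  if (isTRUE(st$analyze)) {
    if (!file.exists(file.path(out_dir, "features.csv")))
      stopf("stage 'analyze' is missing upstream artifact 'features.csv'")
    if (force || !stage_fresh(out_dir, "analyze", h_an,
                              c("mood_rates.csv", "daylevel_models.csv"))) {
      stage_analyze(config, out_dir)
      stage_stamp(out_dir, "analyze", h_an)
      ran <- c(ran, "analyze")
    }
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   list.files(out_dir, pattern = "^\\.stage_"))
  manifest <- list(seed = config$seed, config_hash = h_an,
                   stages_run = ran, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_features <- function(config, out_dir) {
  cohort <- read.csv(file.path(out_dir, "cohort.csv"), stringsAsFactors = FALSE)
  cc <- as_cohort_config(config)
  pp <- config$preprocess
  jitter <- if (is.null(pp$jitter_sd) || is.na(pp$jitter_sd)) cc$gps_noise_sd else
    pp$jitter_sd
  feats <- list(); hourly <- list(); segs <- list(); vals <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    pdir <- file.path(out_dir, "gps", p$id)
    for (fp in list.files(pdir, full.names = TRUE)) {
      date <- as.Date(sub("[.]csv$", "", basename(fp)))
      fixes <- read_beiwe_csv(fp)
      day_start <- as.numeric(as.POSIXct(date, tz = "UTC")) - cc$tz_offset_h * 3600
      res <- process_day(fixes, p$home_lat, p$home_lon, day_start,
                         max_error_m = pp$max_error_m,
                         n_sim = pp$n_imputations, jitter_sd = jitter,
                         min_valid_hours = pp$min_valid_hours,
                         cluster_radius_m = config$features$cluster_radius_m,
                         seed = split_seed(config$seed, 301, i, as.integer(date)),
                         hourly = TRUE)
      feats[[length(feats) + 1]] <-
        cbind(participant_id = p$id, date = as.character(date), res$features)
      vals[[length(vals) + 1]] <-
        data.frame(participant_id = p$id, date = as.character(date),
                   valid_hours = res$validity$valid_hours,
                   included = res$validity$included)
      if (!is.null(res$hourly))
        hourly[[length(hourly) + 1]] <-
          cbind(participant_id = p$id, date = as.character(date), res$hourly)
      if (res$validity$included) {
        fx <- filter_accuracy(fixes, pp$max_error_m)
        pr <- project_to_meters(fx$lat, fx$lon, p$home_lat, p$home_lon)
        b <- bin_10s(data.frame(t = fx$t, x = pr$x, y = pr$y), day_start = day_start)
        sg <- classify_states(b)
        segs[[length(segs) + 1]] <-
          cbind(participant_id = p$id, date = as.character(date), sg)
      }
    }
  }
  wr <- function(lst, nm) write.csv(do.call(rbind, lst),
                                    file.path(out_dir, nm), row.names = FALSE)
  wr(feats, "features.csv"); wr(vals, "validity.csv")
  wr(hourly, "features_hourly.csv"); wr(segs, "segments.csv")
}

stage_spectral <- function(config, out_dir) {
  hourly <- read.csv(file.path(out_dir, "features_hourly.csv"),
                     stringsAsFactors = FALSE)
  cohort <- read.csv(file.path(out_dir, "cohort.csv"), stringsAsFactors = FALSE)
  sp <- config$spectral
  start <- as.Date(config$cohort$start_date)
  hourly$t_days <- as.numeric(as.Date(hourly$date) - start) + hourly$hour / 24
  peaks_all <- list(); peak_sets <- list(lv = list(), entropy = list())
  for (pid in unique(hourly$participant_id)) {
    sub <- hourly[hourly$participant_id == pid, ]
    for (feat in c("lv", "entropy")) {
      pk <- window_spectral_summary(sub$t_days, sub[[feat]],
                                    window_days = sp$window_days,
                                    granularity = sp$granularity, k = sp$k)
      if (is.null(pk)) next
      peak_sets[[feat]][[pid]] <- pk
      peaks_all[[length(peaks_all) + 1]] <-
        cbind(participant_id = pid, feature = feat, window_days = sp$window_days, pk)
    }
  }
  write.csv(do.call(rbind, peaks_all), file.path(out_dir, "spectra.csv"),
            row.names = FALSE)
  cons <- list()
  for (g in unique(cohort$group)) {
    ids <- cohort$id[cohort$group == g]
    for (feat in c("lv", "entropy")) {
      sets <- peak_sets[[feat]][names(peak_sets[[feat]]) %in% ids]
      if (!length(sets)) next
      ct <- cohort_period_consensus(sets, group_size = length(ids),
                                    tol = sp$consensus_tol)
      if (nrow(ct)) cons[[length(cons) + 1]] <- cbind(group = g, feature = feat, ct)
    }
  }
  write.csv(if (length(cons)) do.call(rbind, cons) else
    data.frame(group = character(), feature = character()),
    file.path(out_dir, "consensus.csv"), row.names = FALSE)
}

stage_analyze <- function(config, out_dir) {
  feats <- read.csv(file.path(out_dir, "features.csv"), stringsAsFactors = FALSE)
  cohort <- read.csv(file.path(out_dir, "cohort.csv"), stringsAsFactors = FALSE)
  ema <- ema_daily_table(read_ema_csv(file.path(out_dir, "ema.csv")))
  feats$date <- as.Date(feats$date); ema$date <- as.Date(ema$date)
  pd <- person_day_table(feats, ema, cohort)
  pats <- pd[pd$group %in% c("BP", "MDD"), ]
  rates <- list()
  add_rate <- function(label, rows, item) {
    r <- tryCatch(mood_fluctuation_rate(rows, item), error = function(e) NULL)
    if (!is.null(r)) rates[[length(rates) + 1]] <<-
        data.frame(summary = label, percent = r$percent,
                   n_days = r$n_days, n_total = r$n_total)
  }
  add_rate("depression, patients", pats, "depressed")
  add_rate("depression, controls", pd[pd$group == "HC", ], "depressed")
  add_rate("mania, BP", pd[pd$group == "BP", ], "manic")
  write.csv(do.call(rbind, rates), file.path(out_dir, "mood_rates.csv"),
            row.names = FALSE)
  models <- list()
  for (strat in c("all", "weekday", "weekend")) {
    m <- tryCatch(fit_daylevel_logistic(pats, stratum = strat,
                                        vif_threshold = config$analyze$vif_threshold,
                                        cluster_robust = config$analyze$cluster_robust),
                  error = function(e) NULL)
    if (!is.null(m)) models[[length(models) + 1]] <-
        cbind(model = m$model_id, n = m$n, m$terms)
  }
  write.csv(do.call(rbind, models), file.path(out_dir, "daylevel_models.csv"),
            row.names = FALSE)
  # participant-window spectrum models: max power vs window mood status
  spectra <- tryCatch(read.csv(file.path(out_dir, "spectra.csv"),
                               stringsAsFactors = FALSE), error = function(e) NULL)
  smodels <- list()
  if (!is.null(spectra) && nrow(spectra)) {
    maxp <- spectra[spectra$rank == 1, c("participant_id", "feature", "power")]
    wd <- config$spectral$window_days
    win <- pd[as.numeric(pd$date - as.Date(config$cohort$start_date)) < wd, ]
    stat <- aggregate(cbind(depressed, manic) ~ participant_id, data = win,
                      FUN = function(x) any(x, na.rm = TRUE))
    for (feat in c("lv", "entropy")) {
      rows <- merge(maxp[maxp$feature == feat, ], stat, by = "participant_id")
      rows <- merge(rows, cohort[, c("id", "age", "sex", "employment",
                                     "antidepressant")],
                    by.x = "participant_id", by.y = "id")
      rows$employee_or_student <- as.integer(rows$employment %in%
                                               c("employed", "student"))
      names(rows)[names(rows) == "power"] <- paste0(feat, "_max_power")
      for (oc in c("depressed", "manic")) for (mod in c(1, 4)) {
        m <- tryCatch(fit_spectrum_logistic(rows, paste0(feat, "_max_power"),
                                            outcome = oc, model = mod),
                      error = function(e) NULL)
        if (!is.null(m)) smodels[[length(smodels) + 1]] <-
            cbind(model = m$model_id, feature = feat, n = m$n, m$terms)
      }
    }
  }
  write.csv(if (length(smodels)) do.call(rbind, smodels) else
    data.frame(model = character()),
    file.path(out_dir, "spectrum_models.csv"), row.names = FALSE)
}
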