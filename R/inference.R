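#' Mood-fluctuation day rate
#'
#' Percentage of scored person-days on which an EMA item exceeds 1 (the
#' "not at all" anchor), with the raw counts alongside.
#'
#' @param rows person-day data.frame.
#' @param item column name of the EMA item or status flag; logical flags and
#'   1-5 scores are both accepted (a score above 1 counts as a mood day).
#' @return list `percent`, `n_days` (item > 1), `n_total` (item scored).
#' @export
mood_fluctuation_rate <- function(rows, item) {
  x <- rows[[item]]
  if (is.null(x)) stopf("no column '%s'", item)
  x <- x[!is.na(x)]
  if (!length(x)) stopf("no scored days for item '%s'", item)
  n_days <- if (is.logical(x)) sum(x) else sum(x > 1)
  list(percent = 100 * n_days / length(x), n_days = n_days, n_total = length(x))
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom (wraps `stats::kruskal.test`).
#'
#' @param samples list of numeric vectors, one per group (each nonempty).
#' @return list `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2) stopf("need at least 2 groups")
  if (any(vapply(samples, length, 1L) == 0)) stopf("every group must be nonempty")
  pooled <- unlist(samples)
  if (length(unique(pooled)) == 1) {
    # complete ties: no rank variation, H is 0 by convention
    return(list(H = 0, p = 1, df = length(samples) - 1))
  }
  kt <- kruskal.test(samples)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Mann-Whitney U test with pooled mean ranks
#'
#' Mid-ranks for ties, two-sided normal-approximation p-value with tie
#' correction, and the two group mean ranks over the pooled ranking (the
#' form in which group comparisons of spectral power are reported).
#'
#' @param a,b numeric samples (nonempty).
#' @return list `U` (for sample `a`), `p`, `mean_rank_a`, `mean_rank_b`.
#' @export
mann_whitney_mean_ranks <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(n1)])
  U <- ra - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  p <- if (sig2 <= 0) 1 else 2 * pnorm(-abs(U - mu) / sqrt(sig2))
  list(U = U, p = min(1, p),
       mean_rank_a = ra / n1, mean_rank_b = sum(r[-seq_len(n1)]) / n2)
}

#' Feature-mood Pearson correlations by aggregation timescale
#'
#' Averages each feature and the EMA score within windows of the chosen
#' length (per participant), pools the window means, and reports Pearson r
#' with a two-sided p per feature. A zero-variance side yields an undefined
#' (NA) correlation flag rather than an error.
#'
#' @param data data.frame with `participant_id`, `day`, the feature columns
#'   and the EMA column.
#' @param feature_cols character vector of feature column names.
#' @param ema_col EMA column name (default `"ema"`).
#' @param window `"daily"`, `"weekly"`, `"monthly"`, or `"semiannual"`
#'   (1 / 7 / 28 / 182 days).
#' @return data.frame `feature`, `r`, `p`, `n`, `undefined`.
#' @export
correlate_by_timescale <- function(data, feature_cols, ema_col = "ema",
                                   window = c("daily", "weekly", "monthly",
                                              "semiannual")) {
  window <- match.arg(window)
  len <- c(daily = 1, weekly = 7, monthly = 28, semiannual = 182)[[window]]
  key <- interaction(data$participant_id, ceiling(data$day / len), drop = TRUE)
  out <- lapply(feature_cols, function(fc) {
    fm <- tapply(data[[fc]], key, mean, na.rm = TRUE)
    em <- tapply(data[[ema_col]], key, mean, na.rm = TRUE)
    ok <- !is.na(fm) & !is.na(em)
    fm <- fm[ok]; em <- em[ok]
    if (length(fm) < 3) stopf("fewer than 3 aggregated pairs for '%s'", fc)
    if (sd(fm) == 0 || sd(em) == 0)
      return(data.frame(feature = fc, r = NA_real_, p = NA_real_,
                        n = length(fm), undefined = TRUE))
    ct <- cor.test(fm, em)
    data.frame(feature = fc, r = unname(ct$estimate), p = ct$p.value,
               n = length(fm), undefined = FALSE)
  })
  do.call(rbind, out)
}

# VIF of each column of X given the others: 1 / (1 - R^2_i).
vif_values <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(i) {
    fit <- lm.fit(cbind(1, X[, -i, drop = FALSE]), X[, i])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, i] - mean(X[, i]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly drops the feature with the largest VIF until all remaining
#' VIFs are at or below `threshold`. Perfectly collinear columns (infinite
#' VIF) are dropped first.
#'
#' @param X numeric matrix or data.frame of candidate features (n > columns).
#' @param threshold VIF threshold (default 3).
#' @return character vector of retained column names, with the final VIFs as
#'   attribute `"vif"`.
#' @export
vif_prune <- function(X, threshold = 3) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stopf("need at least 2 features")
  if (nrow(X) <= ncol(X)) stopf("need more rows than features")
  keep <- names(X)
  repeat {
    if (length(keep) < 2) break
    v <- vif_values(X[keep])
    if (max(v) <= threshold) break
    keep <- keep[-which.max(v)]
  }
  structure(keep, vif = if (length(keep) >= 2)
    setNames(vif_values(X[keep]), keep) else setNames(1, keep))
}

# Shared logistic-fit core: Wald CIs, separation guard, tidy output.
fit_logistic <- function(formula, data, model_id, cluster = NULL) {
  mf <- stats::model.frame(formula, data = data, na.action = na.omit)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2)
    stopf("outcome is constant after filtering; cannot fit")
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  co <- coef(fit)
  pr <- fitted(fit)
  yy <- fit$y
  separated <- all(pr[yy == 1] > 1 - 1e-6) && all(pr[yy == 0] < 1e-6)
  if (separated || any(abs(co[-1]) > 15) || !fit$converged) {
    X <- stats::model.matrix(fit)[, -1, drop = FALSE]
    scaled <- abs(co[-1]) * apply(X, 2, sd)
    bad <- names(scaled)[which.max(scaled)]
    stopf("complete or quasi-complete separation on term '%s'", bad)
  }
  V <- if (!is.null(cluster)) {
    if (!requireNamespace("sandwich", quietly = TRUE))
      stopf("cluster-robust errors require the 'sandwich' package")
    sandwich::vcovCL(fit, cluster = cluster)
  } else vcov(fit)
  se <- sqrt(diag(V))
  z <- co / se
  res <- data.frame(term = names(co), beta = unname(co), se = unname(se),
                    p = unname(2 * pnorm(-abs(z))),
                    or = unname(exp(co)),
                    ci_lo = unname(exp(co - qnorm(0.975) * se)),
                    ci_hi = unname(exp(co + qnorm(0.975) * se)),
                    stringsAsFactors = FALSE)
  structure(list(terms = res, n = nrow(mf), model_id = model_id,
                 fit = fit), class = "mobility_logit")
}

#' @export
print.mobility_logit <- function(x, digits = 3, ...) {
  cat(sprintf("<mobility_logit> %s, n = %d person-units\n", x$model_id, x$n))
  tr <- x$terms
  tr$beta <- signif(tr$beta, digits); tr$or <- signif(tr$or, digits)
  tr$ci_lo <- signif(tr$ci_lo, digits); tr$ci_hi <- signif(tr$ci_hi, digits)
  tr$p <- signif(tr$p, 2); tr$se <- NULL
  print(tr, row.names = FALSE)
  invisible(x)
}

#' Person-day logistic model of depressive status on mobility features
#'
#' Fits depressed-day status (EMA depression > 1) on sex, age, the
#' employee-or-student flag, and the VIF-retained mobility features, over
#' all days or a weekday/weekend stratum. Repeated person-days are treated
#' as independent by default (the conventional person-day analysis); set
#' `cluster_robust = TRUE` for cluster-robust (by participant) standard
#' errors. TT and homestay enter as fractions in `[0, 1]`.
#'
#' @param rows person-day data.frame (see [simulate_person_days()] /
#'   [person_day_table()]): flags, features and covariates.
#' @param stratum `"all"`, `"weekday"`, or `"weekend"`.
#' @param features feature columns to offer; defaults to all eight, then
#'   pruned by [vif_prune()] at `vif_threshold`.
#' @param vif_threshold VIF threshold (default 3).
#' @param cluster_robust use participant-clustered standard errors.
#' @return a `mobility_logit`: tidy `terms` table (beta, p, OR, 95% CI),
#'   `n`, and the retained features as attribute `"features"`.
#' @export
fit_daylevel_logistic <- function(rows, stratum = c("all", "weekday", "weekend"),
                                  features = NULL, vif_threshold = 3,
                                  cluster_robust = FALSE) {
  stratum <- match.arg(stratum)
  rows <- switch(stratum, all = rows,
                 weekday = rows[rows$weekday, ],
                 weekend = rows[!rows$weekday, ])
  rows <- rows[!is.na(rows$depressed), ]
  if (!nrow(rows) || length(unique(rows$depressed)) < 2)
    stopf("both outcome classes must be present in stratum '%s'", stratum)
  feats <- features %||% c("lv", "sm", "sv", "nc", "entropy", "homestay", "tt", "td")
  feats <- feats[vapply(feats, function(f) !anyNA(rows[[f]]) && sd(rows[[f]]) > 0,
                        TRUE)]
  if (is.null(features) && length(feats) >= 2)
    feats <- as.character(vif_prune(rows[feats], threshold = vif_threshold))
  rows$sex_male <- as.integer(rows$sex == "M")
  fml <- stats::reformulate(c("sex_male", "age", "employee_or_student", feats),
                            response = "depressed")
  out <- fit_logistic(fml, rows, paste0("day-level/", stratum),
                      cluster = if (cluster_robust) rows$participant_id)
  attr(out, "features") <- feats
  out
}

#' Logistic models of affective status on Fourier spectrum power
#'
#' Fits a window-level EMA status flag on the maximum spectral power of a
#' mobility feature, under the four nested covariate sets: model 1 no
#' adjustment; model 2 age and sex; model 3 plus work; model 4 plus
#' antidepressant use. ORs are reported per raw power unit; the OR per
#' standard deviation of the predictor is attached as attribute
#' `"or_per_sd"`.
#'
#' @param rows participant-window data.frame with the predictor column, the
#'   outcome flag, and covariates `age`, `sex`, `employee_or_student`,
#'   `antidepressant`.
#' @param predictor predictor column, e.g. `"lv_max_power"`.
#' @param outcome outcome flag column, e.g. `"depressed"`.
#' @param model covariate set, 1-4.
#' @return a `mobility_logit`.
#' @export
fit_spectrum_logistic <- function(rows, predictor, outcome = "depressed",
                                  model = 1) {
  if (!model %in% 1:4) stopf("'model' must be 1, 2, 3, or 4")
  rows$sex_male <- as.integer(rows$sex == "M")
  covs <- list(character(), c("age", "sex_male"),
               c("age", "sex_male", "employee_or_student"),
               c("age", "sex_male", "employee_or_student", "antidepressant"))[[model]]
  fml <- stats::reformulate(c(predictor, covs), response = outcome)
  out <- fit_logistic(fml, rows, sprintf("spectrum/%s/model %d", outcome, model))
  s <- sd(rows[[predictor]], na.rm = TRUE)
  beta <- out$terms$beta[out$terms$term == predictor]
  attr(out, "or_per_sd") <- exp(beta * s)
  out
}

#' Required sample size for detecting a correlation (Fisher z)
#'
#' `n = ceil(((z_{1-alpha/2} + z_power) / C)^2) + 3` with
#' `C = atanh(r) = 0.5 * log((1 + r) / (1 - r))`. At r = 0.5, alpha = .05,
#' power = .90 this gives 38.
#'
#' @param r anticipated correlation, in (0, 1).
#' @param alpha two-sided type-I level, in (0, 1).
#' @param power desired power, in (0, 1).
#' @return required sample size (integer).
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.90) {
  for (nm in c("r", "alpha", "power")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1)
      stopf("'%s' must lie strictly in (0, 1)", nm)
  }
  C <- atanh(r)
  as.integer(ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / C)^2) + 3)
}

#' Assemble the analysis-ready person-day table
#'
#' Joins daily mobility features, resolved daily EMA scores, and participant
#' covariates into one row per included participant-day, adding the weekday
#' flag (Monday-Friday, local dates) and the EMA > 1 status flags.
#'
#' @param features_df daily feature table (`participant_id`, `date`,
#'   features, `included`).
#' @param ema_df one row per participant-day with `ema_dep`, `ema_mania`,
#'   `ema_fatigue`, `ema_irrit` (see `ema_daily_table` / [read_ema_csv()]).
#' @param cohort_df participant covariates from [generate_cohort()].
#' @return a person-day data.frame suitable for [fit_daylevel_logistic()].
#' @export
person_day_table <- function(features_df, ema_df, cohort_df) {
  df <- merge(features_df, ema_df, by = c("participant_id", "date"))
  cov <- cohort_df[, c("id", "group", "age", "sex", "employment", "antidepressant")]
  names(cov)[1] <- "participant_id"
  df <- merge(df, cov, by = "participant_id")
  df <- df[df$included %in% TRUE, ]
  wd <- as.POSIXlt(as.Date(df$date))$wday
  df$weekday <- wd >= 1 & wd <= 5
  df$employee_or_student <- as.integer(df$employment %in% c("employed", "student"))
  for (fl in c(depressed = "ema_dep", manic = "ema_mania",
               fatigued = "ema_fatigue", irritable = "ema_irrit")) {
    flag <- names(which(c(depressed = "ema_dep", manic = "ema_mania",
                          fatigued = "ema_fatigue", irritable = "ema_irrit") == fl))
    df[[flag]] <- ifelse(is.na(df[[fl]]), NA, df[[fl]] > 1)
  }
  df
}
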