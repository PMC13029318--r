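#' Fold-error statistics of predicted vs observed values
#'
#' The geometric mean fold error `GMFE = 10^mean(|log10(pred/obs)|)` is a
#' magnitude-of-error measure (always >= 1); the average fold error
#' `AFE = 10^mean(log10(pred/obs))` is its signed counterpart and measures
#' bias (1 = unbiased).  A prediction within a factor of two of every
#' observation has GMFE <= 2.
#'
#' @param observed,predicted Positive numeric vectors of equal length (any
#'   consistent unit; both statistics are unit-free).
#' @return A list with elements `gmfe` and `afe`.
#' @export
#' @examples
#' fold_errors(c(10, 10), c(20, 5))  # GMFE 2, AFE 1
fold_errors <- function(observed, predicted) {
  if (!length(observed) || length(observed) != length(predicted))
    stop("'observed' and 'predicted' must be non-empty and of equal length")
  if (any(!is.finite(observed)) || any(!is.finite(predicted)) ||
      any(observed <= 0) || any(predicted <= 0))
    stop("fold errors require positive observed and predicted values")
  lr <- log10(predicted / observed)
  list(gmfe = 10^mean(abs(lr)), afe = 10^mean(lr))
}

#' Weighted and percentage residuals with study-level summaries
#'
#' Point-level residuals: weighted residual `WRi = (Yo - Yp) / Sp` (needs a
#' per-point standard deviation), percentage error
#' `PE% = (Yo - Yp) / Yo * 100`, and their absolute values `AWRi`, `APE%`.
#' Study-level summaries: `MWRi`/`MAWRi` are medians of WRi/AWRi; `MPE%`
#' and `MAPE%` are means of PE%/APE%; `MdPE%`/`MdAPE%` their medians.
#'
#' @param data Data frame with columns `study_id`, `observed`, `predicted`
#'   and optionally `sd` (per-point observed standard deviation, required
#'   for the weighted-residual family; must be positive where present).
#' @return A list with `points` (the input plus `wri`, `awri`, `pe_pct`,
#'   `ape_pct`) and `by_study` (one row per study with `mwri`, `mawri`,
#'   `mpe_pct`, `mdpe_pct`, `mape_pct`, `mdape_pct`).
#' @export
#' @examples
#' residual_metrics(data.frame(study_id = "a", observed = 10,
#'                             predicted = 8, sd = 1))
residual_metrics <- function(data) {
  need <- c("study_id", "observed", "predicted")
  if (!all(need %in% names(data)))
    stop("'data' must have columns: ", paste(need, collapse = ", "))
  if (any(data$observed == 0))
    stop("observed value of 0: percentage error undefined")
  pts <- data
  if ("sd" %in% names(pts) && any(!is.na(pts$sd))) {
    if (any(pts$sd[!is.na(pts$sd)] <= 0))
      stop("per-point standard deviations must be positive")
    pts$wri <- (pts$observed - pts$predicted) / pts$sd
  } else {
    pts$wri <- NA_real_
  }
  pts$awri <- abs(pts$wri)
  pts$pe_pct <- (pts$observed - pts$predicted) / pts$observed * 100
  pts$ape_pct <- abs(pts$pe_pct)
  med <- function(x) if (all(is.na(x))) NA_real_ else
    stats::median(x, na.rm = TRUE)
  by_study <- do.call(rbind, lapply(split(pts, pts$study_id), function(s)
    data.frame(study_id = s$study_id[1],
               mwri = med(s$wri), mawri = med(s$awri),
               mpe_pct = mean(s$pe_pct), mdpe_pct = stats::median(s$pe_pct),
               mape_pct = mean(s$ape_pct),
               mdape_pct = stats::median(s$ape_pct))))
  rownames(by_study) <- NULL
  list(points = pts, by_study = by_study)
}

#' Signed-rank test of zero-median residuals
#'
#' Two-sided Wilcoxon signed-rank test that the residuals are distributed
#' around zero: exact for up to 25 non-zero residuals (when the absolute
#' values are untied), normal approximation (without continuity correction)
#' otherwise.  Zero residuals are dropped, as usual for the signed-rank
#' statistic.
#'
#' @param residuals Numeric vector.
#' @return A list with `statistic` (V, the sum of positive ranks), `p_value`,
#'   `n` (non-zero residuals used) and `small_sample` (`TRUE` when fewer
#'   than 5 non-zero residuals make the test uninformative).
#' @export
#' @examples
#' wilcoxon_zero_median(1:6)  # V = 21, p = 0.03125
wilcoxon_zero_median <- function(residuals) {
  x <- residuals[is.finite(residuals)]
  x <- x[x != 0]
  if (!length(x)) stop("all residuals are zero: test degenerate")
  small <- length(x) < 5
  if (small)
    warning("fewer than 5 non-zero residuals: p-value is uninformative")
  wt <- suppressWarnings(
    stats::wilcox.test(x, mu = 0, alternative = "two.sided",
                       exact = length(x) <= 25, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(x), small_sample = small)
}

#' Confidence interval for the geometric mean ratio, pooled data
#'
#' `CI = GMR * exp(-+ t(1 - alpha/2, nu) * sqrt(Vobs/nobs + Vpred/npred))`
#' where the means and variances are on the natural-log scale and
#' `GMR = exp(mean_log_pred - mean_log_obs)`.  Degrees of freedom come from
#' the Welch-Satterthwaite approximation of the two variance terms.  The
#' interval is classified against the bioequivalence-style acceptance range
#' 0.80-1.25: `accepted` when fully inside, `rejected` when fully outside,
#' `inconclusive` otherwise.
#'
#' @param obs,pred Either a numeric vector of positive raw values, or a list
#'   with elements `mean`, `var`, `n` giving the log-scale mean, log-scale
#'   variance and sample size of the arm.
#' @param alpha Significance level (default 0.10 for a 90% CI).
#' @return A list with `gmr`, `lower`, `upper`, `df` and `classification`.
#' @export
#' @examples
#' gmr_confidence_interval(c(10, 12, 11), c(11, 13, 10))
gmr_confidence_interval <- function(obs, pred, alpha = 0.10) {
  arm <- function(x, name) {
    if (is.numeric(x)) {
      if (any(x <= 0)) stop("'", name, "' raw values must be positive")
      list(mean = mean(log(x)), var = stats::var(log(x)), n = length(x))
    } else if (is.list(x) && all(c("mean", "var", "n") %in% names(x))) {
      x
    } else stop("'", name, "' must be a numeric vector or a ",
                "list(mean, var, n)")
  }
  o <- arm(obs, "obs"); p <- arm(pred, "pred")
  if (o$n < 2) stop("observed arm needs n >= 2")
  if (o$var < 0 || p$var < 0) stop("variances must be non-negative")
  gmr <- exp(p$mean - o$mean)
  se2 <- o$var / o$n + p$var / p$n
  if (se2 == 0) {
    lo <- hi <- gmr
    df <- NA_real_
  } else {
    a <- o$var / o$n; b <- p$var / p$n
    df <- se2^2 / (a^2 / (o$n - 1) + b^2 / max(p$n - 1, 1))
    half <- stats::qt(1 - alpha / 2, df) * sqrt(se2)
    lo <- gmr * exp(-half); hi <- gmr * exp(half)
  }
  cls <- if (lo >= 0.80 && hi <= 1.25) "accepted"
  else if (hi < 0.80 || lo > 1.25) "rejected"
  else "inconclusive"
  list(gmr = gmr, lower = lo, upper = hi, df = df, classification = cls)
}

#' Two-fold prediction criterion
#'
#' Fraction of predictions within a factor of two of the observation
#' (`0.5 <= pred/obs <= 2`, bounds inclusive) — the conventional coarse
#' acceptance criterion for whole-body PK model predictions.
#'
#' @inheritParams fold_errors
#' @return A list with `fraction` and the per-pair logical vector `pass`.
#' @export
two_fold_check <- function(observed, predicted) {
  if (!length(observed) || length(observed) != length(predicted))
    stop("'observed' and 'predicted' must be non-empty and of equal length")
  if (any(observed <= 0) || any(predicted <= 0))
    stop("two-fold check requires positive values")
  ratio <- predicted / observed
  pass <- ratio >= 0.5 & ratio <= 2
  list(fraction = mean(pass), pass = pass, ratio = ratio)
}

#' Qualify model predictions against observed concentration-time data
#'
#' Runs the full qualification suite on a set of observed series: simulates
#' each study's regimen, interpolates the prediction log-linearly at the
#' observed times, and assembles fold errors on AUC(0-last), residual
#' summaries, signed-rank bias tests and per-study GMR confidence-interval
#' classifications.
#'
#' @param observed Observed data frame in the format of
#'   [read_observed_csv()]: columns `study_id`, `dose_mg_kg`, `route`,
#'   `infusion_h`, `time_h`, `conc_ug_ml` and optional `sd_ug_ml`.
#' @param model A [pbpk_model()] (fitted or default).
#' @param alpha Significance level for the GMR intervals.
#' @return An object of class `validation_report`: a list with `pairs`
#'   (per-study observed/predicted AUC(0-last)), `fold` (gmfe/afe),
#'   `residuals` (see [residual_metrics()]), `wilcoxon_wri`, `wilcoxon_pe`,
#'   `gmr` (per-study CI classification on AUC), `two_fold`.
#' @export
validation_report <- function(observed, model = pbpk_model(), alpha = 0.10) {
  obs <- validate_observed(observed)
  per_study <- lapply(split(obs, obs$study_id), function(s) {
    s <- s[order(s$time_h), ]
    reg <- dose_regimen(s$dose_mg_kg[1], interval_h = max(s$time_h) + 1,
                        n_doses = 1,
                        infusion_h = if (s$route[1] == "infusion")
                          s$infusion_h[1] else 0)
    pred <- predict(model, reg, times = s$time_h)$plasma_conc_ug_ml
    auc_obs <- auc_trapezoid(s$time_h, s$conc_ug_ml)
    auc_pred <- auc_trapezoid(s$time_h, pred)
    list(study_id = s$study_id[1], obs = s$conc_ug_ml, pred = pred,
         sd = if ("sd_ug_ml" %in% names(s)) s$sd_ug_ml else NA_real_,
         auc_obs = auc_obs, auc_pred = auc_pred)
  })
  pairs <- data.frame(
    study_id = vapply(per_study, `[[`, "", "study_id"),
    auc_obs = vapply(per_study, `[[`, 0, "auc_obs"),
    auc_pred = vapply(per_study, `[[`, 0, "auc_pred"))
  pts <- do.call(rbind, lapply(per_study, function(s)
    data.frame(study_id = s$study_id, observed = s$obs, predicted = s$pred,
               sd = s$sd)))
  res <- residual_metrics(pts)
  gmr <- lapply(per_study, function(s)
    gmr_confidence_interval(s$obs, s$pred, alpha = alpha))
  wri <- res$points$wri[is.finite(res$points$wri)]
  rep <- list(
    pairs = pairs,
    fold = fold_errors(pairs$auc_obs, pairs$auc_pred),
    residuals = res,
    wilcoxon_wri = if (length(wri) >= 1 && any(wri != 0))
      wilcoxon_zero_median(wri) else NULL,
    wilcoxon_pe = if (any(res$points$pe_pct != 0))
      wilcoxon_zero_median(res$points$pe_pct) else NULL,
    gmr = gmr,
    two_fold = two_fold_check(pairs$auc_obs, pairs$auc_pred))
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Model qualification report\n")
  cat(sprintf("  %d studies; AUC GMFE %.3f, AFE %.3f; two-fold pass %.0f%%\n",
              nrow(x$pairs), x$fold$gmfe, x$fold$afe,
              100 * x$two_fold$fraction))
  if (!is.null(x$wilcoxon_pe))
    cat(sprintf("  PE%% signed-rank: V = %g, p = %.4f\n",
                x$wilcoxon_pe$statistic, x$wilcoxon_pe$p_value))
  cls <- vapply(x$gmr, `[[`, "", "classification")
  cat("  GMR AUC classifications:",
      paste(sprintf("%s=%s", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

auc_trapezoid <- function(t, y)
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)

validate_observed <- function(observed) {
  need <- c("study_id", "dose_mg_kg", "route", "time_h", "conc_ug_ml")
  if (!all(need %in% names(observed)))
    stop("observed data must have columns: ", paste(need, collapse = ", "))
  if (!"infusion_h" %in% names(observed)) observed$infusion_h <- 0
  for (s in split(observed, observed$study_id)) {
    if (any(diff(sort(s$time_h)) <= 0))
      stop("times must be strictly increasing within study ", s$study_id[1])
    if (any(s$conc_ug_ml < 0))
      stop("negative concentrations in study ", s$study_id[1])
    if ("sd_ug_ml" %in% names(s) &&
        any(!is.na(s$sd_ug_ml) & s$sd_ug_ml <= 0))
      stop("per-point SDs must be positive in study ", s$study_id[1])
  }
  observed
}

#' Read / write observed concentration-time data
#'
#' CSV dialect: `study_id, dose_mg_kg, route, infusion_h, time_h,
#' conc_ug_ml, sd_ug_ml` (route is `bolus` or `infusion`).
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_observed_csv <- function(path) {
  validate_observed(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_observed_csv
#' @param observed Observed data frame.
#' @export
write_observed_csv <- function(observed, path) {
  utils::write.csv(validate_observed(observed), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
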