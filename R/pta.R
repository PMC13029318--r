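#' Efficacy target (PK/PD index and threshold)
#'
#' The two aminoglycoside efficacy indices: peak over MIC (threshold 10) and
#' 24-h AUC over MIC (threshold 50 for non-critical patients, 110 for
#' critical patients or severe infections).  The AUC index uses the day-1
#' 24-h AUC.
#'
#' @param index `"cmax_over_mic"` or `"auc24_over_mic"`.
#' @param threshold Positive number the index must reach (inclusive).
#' @return An object of class `efficacy_target`.
#' @export
#' @examples
#' efficacy_target("auc24_over_mic", 110)
efficacy_target <- function(index = c("cmax_over_mic", "auc24_over_mic"),
                            threshold = NULL) {
  index <- match.arg(index)
  if (is.null(threshold))
    threshold <- switch(index, cmax_over_mic = 10, auc24_over_mic = 50)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  structure(list(index = index, threshold = threshold),
            class = "efficacy_target")
}

.default_mic_grid <- c(0.25, 0.5, 1, 2, 4, 8)

metric_for_index <- function(index) {
  switch(index, cmax_over_mic = "cmax", auc24_over_mic = "auc24_day1",
         stop("unknown PK/PD index '", index, "'"))
}

#' Probability of target attainment
#'
#' For each MIC of the grid and each (stage, dose, interval) group of the
#' exposure table, the percentage of individuals whose PK/PD index value
#' meets or exceeds the target threshold (inclusive comparison).
#'
#' @param metrics Per-individual exposure table from [exposure_grid()] or
#'   [population_exposure()].
#' @param target An [efficacy_target()].
#' @param mic_grid MIC values, ug/mL.
#' @return A data frame with columns `stage`, `dose_mg_kg`, `interval_h`,
#'   `index`, `threshold`, `mic_ug_ml`, `pta_pct`.
#' @export
#' @examples
#' pop <- sample_population(20, seed = 1)
#' m <- exposure_grid(pop, doses = c(2, 6))
#' compute_pta(m, efficacy_target("cmax_over_mic"), mic_grid = c(0.5, 2))
compute_pta <- function(metrics, target = efficacy_target("auc24_over_mic"),
                        mic_grid = .default_mic_grid) {
  if (!nrow(metrics)) stop("empty population")
  stopifnot(inherits(target, "efficacy_target"))
  col <- metric_for_index(target$index)
  if (!col %in% names(metrics))
    stop("metrics table lacks column '", col, "'")
  groups <- unique(metrics[, c("stage", "dose_mg_kg", "interval_h")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- metrics$stage == groups$stage[g] &
      metrics$dose_mg_kg == groups$dose_mg_kg[g] &
      metrics$interval_h == groups$interval_h[g]
    v <- metrics[[col]][sel]
    data.frame(groups[g, , drop = FALSE], index = target$index,
               threshold = target$threshold, mic_ug_ml = mic_grid,
               pta_pct = vapply(mic_grid, function(mic)
                 100 * sum(v / mic >= target$threshold) / length(v),
                 numeric(1)),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Nephrotoxicity risk of a regimen
#'
#' Percentage of the population exceeding (inclusively) a toxicity
#' criterion: 24-h AUC at or above 700 mg.h/L, or trough at or above
#' 0.5 ug/mL.  By default the criterion is assessed on the final dosing
#' interval — with linear kinetics the final interval dominates day 1, so
#' this is the conservative reading of a first-and-third-day assessment;
#' `day_rule = "day1"` assesses the first interval instead.
#'
#' @param metrics Per-individual exposure table.
#' @param criterion `"auc24_ge_700"` or `"cmin_ge_0_5"`.
#' @param day_rule `"final"` or `"day1"`.
#' @return A data frame with columns `stage`, `dose_mg_kg`, `interval_h`,
#'   `criterion`, `risk_pct`.
#' @export
toxicity_risk <- function(metrics,
                          criterion = c("cmin_ge_0_5", "auc24_ge_700"),
                          day_rule = c("final", "day1")) {
  if (!nrow(metrics)) stop("empty population")
  criterion <- match.arg(criterion)
  day_rule <- match.arg(day_rule)
  col <- switch(paste(criterion, day_rule),
                "auc24_ge_700 final" = "auc24_day3",
                "auc24_ge_700 day1" = "auc24_day1",
                "cmin_ge_0_5 final" = "cmin_final",
                "cmin_ge_0_5 day1" = "cmin_day1")
  thr <- switch(criterion, auc24_ge_700 = 700, cmin_ge_0_5 = 0.5)
  groups <- unique(metrics[, c("stage", "dose_mg_kg", "interval_h")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- metrics$stage == groups$stage[g] &
      metrics$dose_mg_kg == groups$dose_mg_kg[g] &
      metrics$interval_h == groups$interval_h[g]
    v <- metrics[[col]][sel]
    data.frame(groups[g, , drop = FALSE], criterion = criterion,
               risk_pct = 100 * sum(v >= thr) / length(v),
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Minimal effective dose per stage and MIC
#'
#' The smallest dose of the grid whose PTA meets or exceeds
#' `pta_threshold` (inclusive), per (stage, interval, index, MIC); `NA`
#' marks combinations for which no dose qualifies.
#'
#' @param pta A [compute_pta()] table.
#' @param doses Dose grid to search; defaults to the doses present.
#' @param pta_threshold Attainment threshold, percent.
#' @return A data frame with columns `stage`, `interval_h`, `index`,
#'   `mic_ug_ml`, `dose_mg_kg` (NA when no dose reaches the threshold).
#' @export
minimal_effective_dose <- function(pta, doses = NULL, pta_threshold = 90) {
  if (is.null(doses)) doses <- sort(unique(pta$dose_mg_kg))
  if (!length(doses)) stop("empty dose list")
  if (!all(doses %in% pta$dose_mg_kg))
    stop("PTA table does not cover all requested doses")
  groups <- unique(pta[, c("stage", "interval_h", "index", "mic_ug_ml")])
  res <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    ok <- vapply(sort(doses), function(d) {
      row <- pta$stage == groups$stage[g] &
        pta$interval_h == groups$interval_h[g] &
        pta$index == groups$index[g] &
        pta$mic_ug_ml == groups$mic_ug_ml[g] &
        pta$dose_mg_kg == d
      any(pta$pta_pct[row] >= pta_threshold)
    }, logical(1))
    data.frame(groups[g, , drop = FALSE],
               dose_mg_kg = if (any(ok)) sort(doses)[which(ok)[1]] else
                 NA_real_,
               row.names = NULL)
  }))
  rownames(res) <- NULL
  res
}

#' Regimens that are both effective and safe
#'
#' For each (stage, MIC), the regimens (dose, interval) with PTA at or above
#' `pta_threshold` and toxicity risk at or below `risk_threshold` (both
#' inclusive), and a flag on the maximal-dose regimen (longest interval
#' among ties), i.e. the extended-interval regimen that preserves the
#' high peak while staying safe.
#'
#' @param pta A [compute_pta()] table.
#' @param tox A [toxicity_risk()] table on the same (stage, dose, interval)
#'   grid.
#' @param pta_threshold,risk_threshold Percent thresholds.
#' @return A data frame with columns `stage`, `mic_ug_ml`, `dose_mg_kg`,
#'   `interval_h`, `pta_pct`, `risk_pct`, `flagged`.
#' @export
recommend_regimen <- function(pta, tox, pta_threshold = 90,
                              risk_threshold = 10) {
  key <- function(df) paste(df$stage, df$dose_mg_kg, df$interval_h)
  if (!setequal(unique(key(pta)), unique(key(tox))))
    stop("PTA and toxicity tables cover different regimen grids")
  merged <- merge(pta, tox[, c("stage", "dose_mg_kg", "interval_h",
                               "risk_pct")],
                  by = c("stage", "dose_mg_kg", "interval_h"))
  ok <- merged[merged$pta_pct >= pta_threshold &
                 merged$risk_pct <= risk_threshold, ]
  if (!nrow(ok)) {
    out <- ok[, c("stage", "mic_ug_ml", "dose_mg_kg", "interval_h",
                  "pta_pct", "risk_pct")]
    out$flagged <- logical(0)
    return(out)
  }
  groups <- unique(ok[, c("stage", "mic_ug_ml")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sub <- ok[ok$stage == groups$stage[g] &
                ok$mic_ug_ml == groups$mic_ug_ml[g], ]
    sub <- sub[order(sub$dose_mg_kg, sub$interval_h), ]
    sub$flagged <- seq_len(nrow(sub)) == nrow(sub)
    sub[, c("stage", "mic_ug_ml", "dose_mg_kg", "interval_h",
            "pta_pct", "risk_pct", "flagged")]
  }))
  rownames(out) <- NULL
  out
}

#' Local sensitivity of AUC and Cmax to model parameters
#'
#' One-at-a-time forward perturbation: each parameter is increased by the
#' fraction `perturbation` and the normalised sensitivity
#' `S = (delta AUC / AUC) / (delta p / p)` is reported (same for Cmax), so
#' +1.0 means a 10% parameter increase raises the output by 10%.  Tissue
#' flows are perturbed with cardiac output adjusted to keep the flow
#' balance; parameters with no pathway into the kinetics (e.g.
#' `molecular_weight`, `pka_acid`) report 0.
#'
#' @param model A [pbpk_model()].
#' @param regimen Regimen under which exposure is evaluated.
#' @param parameters Character vector of parameter names: `"dose"`,
#'   `"gfr"`, `"fu"`, `"kp_scale"`, `"blood_plasma_ratio"`,
#'   `"cl_unspecific"`, `"k_protein"`, `"molecular_weight"`, `"pka_acid"`,
#'   `"weight"`, `"volume_<organ>"` or `"flow_<tissue>"`.
#' @param perturbation Positive fractional perturbation (default 0.1).
#' @return A data frame with columns `parameter`, `s_auc`, `s_cmax`.
#' @export
#' @examples
#' sensitivity_analysis(pbpk_model(), dose_regimen(2, n_doses = 1),
#'                      parameters = c("gfr", "dose"))
sensitivity_analysis <- function(model, regimen = dose_regimen(2),
                                 parameters = c("volume_muscle",
                                                "volume_adipose",
                                                "volume_kidney", "gfr",
                                                "fu", "kp_scale"),
                                 perturbation = 0.1) {
  if (!is.numeric(perturbation) || perturbation <= 0)
    stop("'perturbation' must be positive")
  base <- exposure_metrics(simulate_profile(model, regimen))
  eval_perturbed <- function(par) {
    drug <- model$drug; phys <- model$physiology; reg <- regimen
    f <- 1 + perturbation
    if (par == "dose") {
      reg$dose_per_kg <- reg$dose_per_kg * f
    } else if (par == "gfr") {
      phys$gfr <- phys$gfr * f
    } else if (par == "weight") {
      return(rebuild_and_measure(
        drug, reference_dog(phys$weight * f, phys$gfr,
                            table = phys$organs[, c(
                              "organ", "volume_per_kg", "flow_per_kg",
                              "f_water", "f_lipid", "f_protein")]), reg))
    } else if (par %in% c("fu", "kp_scale", "blood_plasma_ratio",
                          "cl_unspecific", "k_protein",
                          "molecular_weight", "pka_acid")) {
      drug[[par]] <- drug[[par]] * f
    } else if (grepl("^(volume|flow)_", par)) {
      what <- sub("_.*$", "", par)
      org <- sub("^(volume|flow)_", "", par)
      tab <- phys$organs
      i <- match(org, tab$organ)
      if (is.na(i)) stop("unknown organ in parameter '", par, "'")
      col <- paste0(what, "_per_kg")
      tab[[col]][i] <- tab[[col]][i] * f
      if (what == "flow") {
        if (!org %in% .tissue_names)
          stop("only tissue flows can be perturbed: '", par, "'")
        blood <- tab$organ %in% c("arterial_blood", "venous_blood")
        tab$flow_per_kg[blood] <-
          sum(tab$flow_per_kg[match(.tissue_names, tab$organ)])
      }
      return(rebuild_and_measure(
        drug, reference_dog(phys$weight, phys$gfr,
                            table = tab[, c("organ", "volume_per_kg",
                                            "flow_per_kg", "f_water",
                                            "f_lipid", "f_protein")]), reg))
    } else {
      stop("unknown parameter '", par, "'")
    }
    rebuild_and_measure(drug, phys, reg)
  }
  res <- lapply(parameters, eval_perturbed)
  data.frame(
    parameter = parameters,
    s_auc = vapply(res, function(m)
      (m$auc24_day1 / base$auc24_day1 - 1) / perturbation, numeric(1)),
    s_cmax = vapply(res, function(m)
      (m$cmax / base$cmax - 1) / perturbation, numeric(1)))
}

rebuild_and_measure <- function(drug, phys, regimen) {
  exposure_metrics(simulate_profile(pbpk_model(drug, phys), regimen))
}
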