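test_that("PTA equals the brute-force enumeration oracle exactly", {
  set.seed(42)
  n <- 500
  metrics <- data.frame(stage = "healthy", dose_mg_kg = 4, interval_h = 24,
                        auc24_day1 = rlnorm(n, log(20), 0.4),
                        cmax = rlnorm(n, log(15), 0.2))
  for (target in list(efficacy_target("auc24_over_mic", 50),
                      efficacy_target("auc24_over_mic", 110),
                      efficacy_target("cmax_over_mic", 10))) {
    pta <- compute_pta(metrics, target, mic_grid = c(0.25, 0.5, 1, 2, 4, 8))
    col <- if (target$index == "cmax_over_mic") metrics$cmax else
      metrics$auc24_day1
    for (i in seq_len(nrow(pta))) {
      count <- sum(col / pta$mic_ug_ml[i] >= target$threshold)
      expect_identical(pta$pta_pct[i], 100 * count / n)
      expect_equal(pta$pta_pct[i], 100 * mean(
        col / pta$mic_ug_ml[i] >= target$threshold))
    }
  }
})

test_that("PTA comparisons are inclusive at the boundary", {
  metrics <- data.frame(stage = "s", dose_mg_kg = 1, interval_h = 24,
                        auc24_day1 = rep(50, 10), cmax = rep(5, 10))
  pta <- compute_pta(metrics, efficacy_target("auc24_over_mic", 50),
                     mic_grid = c(1, 2))
  expect_equal(pta$pta_pct[pta$mic_ug_ml == 1], 100)  # 50/1 == 50 attains
  expect_equal(pta$pta_pct[pta$mic_ug_ml == 2], 0)
  expect_error(compute_pta(metrics[0, ], efficacy_target("cmax_over_mic")),
               "empty")
})

test_that("toxicity risk equals enumeration and is inclusive", {
  set.seed(7)
  metrics <- data.frame(stage = "s", dose_mg_kg = 8, interval_h = 24,
                        auc24_day1 = runif(200, 300, 900),
                        auc24_day3 = runif(200, 300, 900),
                        cmax = runif(200, 10, 50),
                        cmin_day1 = runif(200, 0, 1),
                        cmin_final = c(0.5, runif(199, 0, 1)))
  tox <- toxicity_risk(metrics, "cmin_ge_0_5")
  expect_identical(tox$risk_pct, 100 * sum(metrics$cmin_final >= 0.5) / 200)
  tox2 <- toxicity_risk(metrics, "auc24_ge_700", day_rule = "day1")
  expect_identical(tox2$risk_pct, 100 * sum(metrics$auc24_day1 >= 700) / 200)
  all_over <- transform(metrics, cmin_final = 1)
  expect_equal(toxicity_risk(all_over, "cmin_ge_0_5")$risk_pct, 100)
  expect_error(toxicity_risk(metrics, "auc_ge_1000"), "should be one of")
})

test_that("PTA is monotone in MIC and dose; risk monotone in dose", {
  pop <- sample_population(40, stage = "upc_ge_2", seed = 9)
  metrics <- exposure_grid(pop, doses = c(2, 4, 6, 8, 10))
  pta <- compute_pta(metrics, efficacy_target("auc24_over_mic", 50))
  for (d in unique(pta$dose_mg_kg)) {
    sub <- pta[pta$dose_mg_kg == d, ]
    expect_true(all(diff(sub$pta_pct[order(sub$mic_ug_ml)]) <= 0))
  }
  for (mic in unique(pta$mic_ug_ml)) {
    sub <- pta[pta$mic_ug_ml == mic, ]
    expect_true(all(diff(sub$pta_pct[order(sub$dose_mg_kg)]) >= 0))
  }
  tox <- toxicity_risk(metrics, "cmin_ge_0_5")
  expect_true(all(diff(tox$risk_pct[order(tox$dose_mg_kg)]) >= 0))
})

test_that("risk does not increase when the dosing interval is extended", {
  pop <- sample_population(30, stage = "scr_ge_2_4", seed = 13)
  risks <- vapply(c(24, 36, 48), function(iv)
    toxicity_risk(exposure_grid(pop, doses = 6, interval_h = iv),
                  "cmin_ge_0_5")$risk_pct, numeric(1))
  expect_true(all(diff(risks) <= 0))
})

test_that("PTA on subsamples stays within 3 points of the full population", {
  metrics <- closed_form_metrics(4000, dose = 6, seed = 31)
  target <- efficacy_target("auc24_over_mic", 50)
  full <- compute_pta(metrics, target, mic_grid = c(0.5, 1))$pta_pct
  for (s in 1:3) {
    set.seed(100 + s)
    sub <- metrics[sample(nrow(metrics), 2000), ]
    subpta <- compute_pta(sub, target, mic_grid = c(0.5, 1))$pta_pct
    expect_true(all(abs(subpta - full) < 3))
  }
})

test_that("minimal effective dose picks the smallest qualifying dose", {
  pta <- expand.grid(stage = "healthy", dose_mg_kg = c(2, 4, 6),
                     interval_h = 24, index = "auc24_over_mic",
                     threshold = 50, mic_ug_ml = c(0.5, 1, 8),
                     stringsAsFactors = FALSE)
  pta$pta_pct <- c(95, 99, 100,   # MIC 0.5: lowest dose already qualifies
                   40, 90, 99,    # MIC 1: exact 90 at 4 qualifies
                   0, 0, 10)      # MIC 8: none
  med <- minimal_effective_dose(pta)
  expect_equal(med$dose_mg_kg[med$mic_ug_ml == 0.5], 2)
  expect_equal(med$dose_mg_kg[med$mic_ug_ml == 1], 4)
  expect_true(is.na(med$dose_mg_kg[med$mic_ug_ml == 8]))
  expect_error(minimal_effective_dose(pta, doses = c(2, 12)), "cover")
  expect_error(minimal_effective_dose(pta, doses = numeric(0)), "empty")
})

test_that("regimen recommendation applies inclusive thresholds", {
  pta <- data.frame(stage = "healthy", dose_mg_kg = c(6, 8, 10),
                    interval_h = 24, index = "auc24_over_mic",
                    threshold = 50, mic_ug_ml = 0.5,
                    pta_pct = c(90, 95, 99))
  tox <- data.frame(stage = "healthy", dose_mg_kg = c(6, 8, 10),
                    interval_h = 24, criterion = "cmin_ge_0_5",
                    risk_pct = c(10, 12, 40))
  rec <- recommend_regimen(pta, tox)
  expect_equal(rec$dose_mg_kg, 6)  # PTA 90 and risk 10 exactly qualify
  expect_true(rec$flagged)
  # empty qualifying set: a result with zero rows, not an error
  none <- recommend_regimen(transform(pta, pta_pct = 50), tox)
  expect_equal(nrow(none), 0)
  bad_tox <- tox[1:2, ]
  expect_error(recommend_regimen(pta, bad_tox), "different regimen grids")
})

test_that("flag goes to the maximal dose, longest interval among ties", {
  pta <- expand.grid(stage = "s", dose_mg_kg = c(8, 10),
                     interval_h = c(24, 36), index = "auc24_over_mic",
                     threshold = 50, mic_ug_ml = 0.5,
                     stringsAsFactors = FALSE)
  pta$pta_pct <- 99
  tox <- expand.grid(stage = "s", dose_mg_kg = c(8, 10),
                     interval_h = c(24, 36), criterion = "cmin_ge_0_5",
                     stringsAsFactors = FALSE)
  tox$risk_pct <- c(5, 15, 2, 6)  # dose 10 q24 unsafe, q36 safe
  rec <- recommend_regimen(pta, tox)
  flagged <- rec[rec$flagged, ]
  expect_equal(flagged$dose_mg_kg, 10)
  expect_equal(flagged$interval_h, 36)
})

test_that("sensitivity analysis recovers analytic elasticities", {
  m <- pbpk_model()
  reg <- dose_regimen(2, n_doses = 1)
  s <- sensitivity_analysis(m, reg,
                            parameters = c("gfr", "dose", "pka_acid",
                                           "molecular_weight"))
  # AUC is dose/CL: elasticity -1 in clearance (forward difference of 1/x
  # at +10% gives -0.909), exactly +1 in dose, 0 for inert parameters
  expect_lt(abs(s$s_auc[s$parameter == "gfr"] - (-1)), 0.15)
  expect_equal(s$s_auc[s$parameter == "dose"], 1, tolerance = 1e-6)
  expect_equal(s$s_cmax[s$parameter == "dose"], 1, tolerance = 1e-6)
  expect_equal(s$s_auc[s$parameter == "pka_acid"], 0)
  expect_equal(s$s_auc[s$parameter == "molecular_weight"], 0)
  # the peak is far less clearance-sensitive than the AUC
  expect_lt(abs(s$s_cmax[s$parameter == "gfr"]), 0.35)
  expect_lt(abs(s$s_cmax[s$parameter == "gfr"]),
            abs(s$s_auc[s$parameter == "gfr"]))
  expect_error(sensitivity_analysis(m, reg, parameters = "magic"),
               "unknown parameter")
  expect_error(sensitivity_analysis(m, reg, perturbation = 0), "positive")
})
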