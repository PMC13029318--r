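test_that("fold errors reproduce hand-computed examples", {
  # single pair: GMFE is just the (larger over smaller) ratio
  fe <- fold_errors(2630.34, 2694.01)
  expect_equal(fe$gmfe, 2694.01 / 2630.34)  # ~1.024
  expect_equal(fe$afe, 2694.01 / 2630.34)
  # perfect predictions
  fe0 <- fold_errors(c(1, 5, 10), c(1, 5, 10))
  expect_equal(fe0$gmfe, 1)
  expect_equal(fe0$afe, 1)
  # two-fold errors in opposite directions cancel in AFE, add in GMFE
  fe2 <- fold_errors(c(10, 10), c(20, 5))
  expect_equal(fe2$gmfe, 2)
  expect_equal(fe2$afe, 1)
  expect_error(fold_errors(c(1, -1), c(1, 1)), "positive")
  expect_error(fold_errors(numeric(0), numeric(0)), "non-empty")
})

test_that("fold-error identities hold on random pair sets", {
  set.seed(5)
  for (i in 1:20) {
    obs <- rlnorm(sample(2:12, 1), 2, 1)
    pred <- obs * rlnorm(length(obs), 0, 0.5)
    fe <- fold_errors(obs, pred)
    expect_gte(fe$gmfe, max(fe$afe, 1 / fe$afe) - 1e-12)
    expect_gte(fe$gmfe, 1)
    # unit invariance: scaling both members leaves both statistics alone
    fe_scaled <- fold_errors(obs * 477.6, pred * 477.6)
    expect_equal(fe_scaled$gmfe, fe$gmfe)
    expect_equal(fe_scaled$afe, fe$afe)
    # a perfect pair pulls GMFE toward 1
    fe_plus <- fold_errors(c(obs, 3), c(pred, 3))
    expect_lte(fe_plus$gmfe, fe$gmfe + 1e-12)
  }
})

test_that("residual metrics reproduce the worked examples", {
  r <- residual_metrics(data.frame(study_id = "a", observed = 10,
                                   predicted = 8, sd = 1))
  expect_equal(r$points$wri, 2)
  expect_equal(r$points$pe_pct, 20)
  r0 <- residual_metrics(data.frame(study_id = "a", observed = 7,
                                    predicted = 7, sd = 2))
  expect_equal(r0$points$wri, 0)
  expect_equal(r0$points$pe_pct, 0)
  # PE% set {10, -30, 20}: MPE 0, MdPE 10, MAPE 20, MdAPE 20
  d <- data.frame(study_id = "s", observed = c(100, 100, 100),
                  predicted = c(90, 130, 80))
  s <- residual_metrics(d)$by_study
  expect_equal(s$mpe_pct, 0)
  expect_equal(s$mdpe_pct, 10)
  expect_equal(s$mape_pct, 20)
  expect_equal(s$mdape_pct, 20)
  expect_true(is.na(s$mwri))  # no SDs supplied
  expect_error(residual_metrics(data.frame(study_id = "a", observed = 0,
                                           predicted = 1)), "undefined")
  expect_error(residual_metrics(data.frame(study_id = "a", observed = 2,
                                           predicted = 1, sd = 0)),
               "positive")
})

test_that("signed-rank test matches the exact distribution", {
  w <- wilcoxon_zero_median(1:6)
  expect_equal(w$statistic, 21)
  expect_equal(w$p_value, 0.03125)
  expect_false(w$small_sample)
  # perfectly antisymmetric residuals: no evidence against zero median
  w2 <- wilcoxon_zero_median(c(1, -1, 2, -2, 3, -3))
  expect_equal(w2$p_value, 1)
  expect_warning(wilcoxon_zero_median(c(1, 2, 3)), "fewer than 5")
  expect_error(wilcoxon_zero_median(c(0, 0, 0)), "degenerate")
})

test_that("signed-rank p-values are super-uniform under the null", {
  set.seed(2024)
  p <- replicate(1500, wilcoxon_zero_median(rnorm(10))$p_value)
  expect_lte(mean(p <= 0.05), 0.05)
})

test_that("GMR confidence intervals collapse, centre and classify", {
  # zero variance: interval collapses onto the GMR
  ci0 <- gmr_confidence_interval(list(mean = log(10), var = 0, n = 5),
                                 list(mean = log(12), var = 0, n = 5))
  expect_equal(ci0$lower, ci0$gmr)
  expect_equal(ci0$upper, ci0$gmr)
  expect_equal(ci0$gmr, 1.2)
  # GMR 1 with symmetric variance: CI symmetric on the log scale
  ci1 <- gmr_confidence_interval(list(mean = 2, var = 0.04, n = 6),
                                 list(mean = 2, var = 0.04, n = 6))
  expect_equal(ci1$gmr, 1)
  expect_equal(log(ci1$upper), -log(ci1$lower))
  expect_equal(ci1$classification, "accepted")
  # wide interval overlapping the acceptance range partially
  ci2 <- gmr_confidence_interval(list(mean = 0, var = 0.5, n = 4),
                                 list(mean = 0.3, var = 0.5, n = 4))
  expect_equal(ci2$classification, "inconclusive")
  # interval entirely outside the range
  ci3 <- gmr_confidence_interval(list(mean = 0, var = 0.001, n = 8),
                                 list(mean = log(3), var = 0.001, n = 8))
  expect_equal(ci3$classification, "rejected")
  expect_error(gmr_confidence_interval(list(mean = 0, var = 1, n = 1),
                                       list(mean = 0, var = 1, n = 5)),
               "n >= 2")
})

test_that("GMR interval width shrinks with the observed sample size", {
  widths <- vapply(c(3, 6, 12, 48), function(n) {
    ci <- gmr_confidence_interval(list(mean = 0, var = 0.09, n = n),
                                  list(mean = 0.1, var = 0.09, n = 6))
    log(ci$upper) - log(ci$lower)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("two-fold check uses inclusive bounds", {
  tf <- two_fold_check(c(1, 1, 1), c(2, 2.01, 0.5))
  expect_equal(tf$pass, c(TRUE, FALSE, TRUE))
  expect_equal(tf$fraction, 2 / 3)
  expect_error(two_fold_check(0, 1), "positive")
})

test_that("qualification report runs end to end on synthetic data", {
  dat <- generate_observed_dataset(
    synthetic_design(n_subjects = 3, noise_cv = 0.15, seed = 8,
                     sample_times = c(0.25, 0.5, 1, 2, 4, 8)))
  rep <- validation_report(dat)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$pairs), 3)
  expect_gte(rep$fold$gmfe, 1)
  expect_true(all(vapply(rep$gmr, `[[`, "", "classification") %in%
                    c("accepted", "inconclusive", "rejected")))
  expect_true(rep$two_fold$fraction >= 0 && rep$two_fold$fraction <= 1)
  # residual summaries exist per study
  expect_equal(nrow(rep$residuals$by_study), 3)
  expect_output(print(rep), "GMFE")
})

test_that("observed CSV round-trips through the reader", {
  dat <- generate_observed_dataset(synthetic_design(n_subjects = 2, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed_csv(dat, path)
  back <- read_observed_csv(path)
  expect_equal(back$conc_ug_ml, dat$conc_ug_ml, tolerance = 1e-9)
  bad <- dat
  bad$time_h[2] <- bad$time_h[1]
  expect_error(write_observed_csv(bad, path), "strictly increasing")
})
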