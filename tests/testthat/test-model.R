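test_that("mass balance holds within 0.1% at every output time", {
  m <- pbpk_model()
  for (reg in list(dose_regimen(10, n_doses = 3),
                   dose_regimen(4, infusion_h = 0, n_doses = 2),
                   dose_regimen(6, interval_h = 48, n_doses = 3))) {
    prof <- simulate_profile(m, reg)
    in_system <- rowSums(prof$amounts) + prof$eliminated
    dosed <- prof$administered
    rel <- abs(in_system - dosed)[dosed > 0] / dosed[dosed > 0]
    expect_lt(max(rel), 0.001)
  }
})

test_that("zero dose produces a zero profile and zero metrics", {
  prof <- simulate_profile(pbpk_model(), dose_regimen(0))
  expect_true(all(prof$conc == 0))
  expect_true(all(exposure_metrics(prof) == 0))
})

test_that("kinetics are linear in dose", {
  m <- pbpk_model()
  p1 <- simulate_profile(m, dose_regimen(2, n_doses = 2))
  p2 <- simulate_profile(m, dose_regimen(4, n_doses = 2))
  expect_equal(p1$time, p2$time)
  # compare where the concentration is numerically meaningful (the solver's
  # absolute tolerance dominates below ~1e-9 ug/mL)
  nz <- p1$conc > 1e-2
  expect_lt(max(abs(p2$conc[nz] / p1$conc[nz] - 2)), 1e-6 * 2)
})

test_that("multi-dose profile is the superposition of shifted single doses", {
  m <- pbpk_model()
  multi <- simulate_profile(m, dose_regimen(2, n_doses = 3))
  single <- simulate_profile(m, dose_regimen(2, interval_h = 72, n_doses = 1))
  # day 1 equals the single-dose profile (no accumulation before dose 2)
  day1 <- multi$time <= 24
  s1 <- vapply(multi$time[day1], function(t)
    single$conc[which.min(abs(single$time - t))], numeric(1))
  expect_equal(multi$conc[day1], s1, tolerance = 1e-6)
  # final interval equals the sum of three shifted copies
  probe <- seq(48.5, 71.5, by = 0.5)
  lookup <- function(t) single$conc[which.min(abs(single$time - t))]
  expected <- vapply(probe, function(t)
    lookup(t) + lookup(t - 24) + lookup(t - 48), numeric(1))
  got <- vapply(probe, function(t)
    multi$conc[which.min(abs(multi$time - t))], numeric(1))
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("lumped limit matches the one-compartment closed form", {
  m <- lumped_model(cl = 0.17)
  reg <- dose_regimen(2, interval_h = 24, n_doses = 1, infusion_h = 0)
  grid <- sort(unique(c(seq(0, 3, by = 0.005), seq(3, 24, by = 0.1))))
  prof <- simulate_profile(m, reg, times = grid)
  v <- lumped_volume(m)         # plasma-referenced blood volume, L
  cl <- m$cl$total              # L/h
  d <- prof$dose_mg             # mg
  # profile: compare after the arterial/venous mixing transient over a
  # 30-fold concentration decline
  sel <- prof$time >= 0.1 & prof$time <= 1.5
  analytic <- d / v * exp(-cl * prof$time[sel] / v)
  expect_lt(max(abs(prof$conc[sel] / analytic - 1)), 0.01)
  # AUC0-inf equals dose / CL within 1%
  auc <- trap_auc(prof$time, prof$conc)
  expect_lt(abs(auc - 2 * 10.5 / cl) / (2 * 10.5 / cl), 0.01)
})

test_that("reducing GFR strictly increases AUC", {
  aucs <- vapply(c(3.33, 2.0, 1.0, 0.33), function(g) {
    m <- pbpk_model(physiology = reference_dog(gfr = g))
    prof <- simulate_profile(m, dose_regimen(2, n_doses = 1))
    trap_auc(prof$time, prof$conc)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("simulation grid contract is enforced", {
  m <- pbpk_model()
  reg <- dose_regimen(2, n_doses = 1)
  expect_error(simulate_profile(m, reg, times = c(1, 2)), "start at 0")
  expect_error(simulate_profile(m, reg, times = c(0, 2, 1)),
               "strictly increasing")
  expect_error(simulate_profile(m, reg, times = c(0, 30)), "beyond")
  grid <- default_time_grid(reg)
  expect_equal(grid[1], 0)
  expect_true(max(grid) == 24)
  expect_true(any(abs(grid - reg$infusion_h) < 1e-12))  # end of infusion
})

test_that("regimen validation rejects impossible designs", {
  expect_error(dose_regimen(-1), "non-negative")
  expect_error(dose_regimen(2, interval_h = 0), "positive")
  expect_error(dose_regimen(2, n_doses = 0), "at least 1")
  expect_error(dose_regimen(2, infusion_h = 24), "infusion_h")
})

test_that("simulate() draws a population at the model's renal stage", {
  m <- pbpk_model(physiology = apply_renal_stage(reference_dog(),
                                                 "scr_ge_5"))
  sim <- simulate(m, nsim = 3, seed = 2, regimen = dose_regimen(10))
  expect_equal(nrow(sim), 3)
  expect_true(all(sim$stage == "scr_ge_5"))
  expect_true(all(sim$cmin_final >= 0.5))  # severe stage accumulates
})

test_that("predict returns concentrations at requested times", {
  m <- pbpk_model()
  out <- predict(m, dose_regimen(2, n_doses = 1), times = c(0.5, 1, 12))
  expect_equal(out$time_h, c(0.5, 1, 12))
  expect_true(all(out$plasma_conc_ug_ml >= 0))
  expect_error(predict(m, dose_regimen(2, n_doses = 1), times = 100),
               "within the regimen")
})
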