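# Shared builders for the test suite.  Everything is generated in code; no
# stored fixtures beyond the package's physiology table.

# A drug whose tissue partitioning is switched off (Kp ~ 0 everywhere), so
# the whole body collapses to the blood pool and the profile has the
# closed-form one-compartment solution C(t) = (D/V) exp(-CL t / V) with
# V = blood volume x blood:plasma ratio.
lumped_drug <- function(cl = 0.17, fu = 0.85) {
  eps <- as.list(rep(1e-6, 5))
  names(eps) <- c("muscle", "adipose", "kidney", "liver", "rest")
  gentamicin(fu = fu, reference_plasma_clearance = cl, kp_overrides = eps)
}

# Healthy dog whose renal clearance per kg equals `cl` exactly.
dog_with_cl <- function(cl = 0.17, fu = 0.85, weight = 10.5) {
  reference_dog(weight = weight, gfr = cl / fu * 1000 / 60)
}

lumped_model <- function(cl = 0.17, weight = 10.5) {
  pbpk_model(lumped_drug(cl), dog_with_cl(cl, weight = weight))
}

# Plasma-referenced blood volume of the lumped model, L.
lumped_volume <- function(model) {
  org <- model$physiology$organs
  sum(org$volume[org$organ %in% c("arterial_blood", "venous_blood")]) *
    model$drug$blood_plasma_ratio
}

# Trapezoidal AUC helper independent of the package internals.
trap_auc <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

# Closed-form per-individual exposure metrics from the two-compartment
# model: a cheap stand-in population for testing the counting statistics
# (PTA, risk) at large n without the ODE solver.
closed_form_metrics <- function(n, dose, cl_mean = 0.17, cv = 0.15,
                                seed = 1, stage = "healthy",
                                interval_h = 24) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  cl <- rlnorm(n, log(cl_mean) - sdlog^2 / 2, sdlog)
  tgrid <- seq(0, 24, by = 0.05)
  cmax <- vapply(cl, function(ci)
    max(two_compartment_conc(tgrid, dose, ci, 0.105, 0.10, 1.35,
                             infusion_h = 0.5)), numeric(1))
  data.frame(individual_id = seq_len(n), stage = stage,
             dose_mg_kg = dose, interval_h = interval_h,
             auc24_day1 = dose / cl, auc24_day3 = dose / cl,
             cmax = cmax,
             cmin_day1 = dose * exp(rnorm(n, -8, 1)),
             cmin_final = dose * exp(rnorm(n, -8, 1)))
}
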