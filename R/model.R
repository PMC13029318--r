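#' Intravenous dose regimen
#'
#' @param dose_per_kg Dose in mg/kg (>= 0).
#' @param interval_h Dosing interval in hours (> 0).
#' @param n_doses Number of doses (>= 1).
#' @param infusion_h Infusion duration in hours; 0 means bolus.  The default
#'   0.5 h is a slow intravenous infusion, the administration that clinical
#'   dosing guidance for aminoglycosides assumes and the one under which the
#'   grid-maximum concentration is the clinically meaningful peak.  Use
#'   `5/60` to mirror the 5-min infusions of some literature study designs.
#' @return An object of class `dose_regimen`.
#' @export
#' @examples
#' dose_regimen(10)                       # 10 mg/kg q24h x3, 30-min infusion
#' dose_regimen(4, interval_h = 48, n_doses = 3, infusion_h = 0)  # bolus
dose_regimen <- function(dose_per_kg, interval_h = 24, n_doses = 3,
                         infusion_h = 0.5) {
  if (!is.numeric(dose_per_kg) || length(dose_per_kg) != 1L ||
      !is.finite(dose_per_kg) || dose_per_kg < 0)
    stop("'dose_per_kg' must be a non-negative number")
  if (!is.finite(interval_h) || interval_h <= 0)
    stop("'interval_h' must be positive")
  if (!is.finite(n_doses) || n_doses < 1)
    stop("'n_doses' must be at least 1")
  if (!is.finite(infusion_h) || infusion_h < 0 || infusion_h >= interval_h)
    stop("'infusion_h' must be in [0, interval_h)")
  structure(list(dose_per_kg = dose_per_kg, interval_h = interval_h,
                 n_doses = as.integer(n_doses), infusion_h = infusion_h),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  adm <- if (x$infusion_h > 0)
    sprintf("%.0f-min infusion", x$infusion_h * 60) else "bolus"
  cat(sprintf("%g mg/kg IV (%s) q%gh x %d\n",
              x$dose_per_kg, adm, x$interval_h, x$n_doses))
  invisible(x)
}

#' Whole-body pharmacokinetic model of a dog
#'
#' Couples a drug parameter set to an individual physiology.  The model is
#' perfusion-limited: each tissue is a well-stirred compartment fed by
#' arterial blood, with the drug leaving at the tissue concentration divided
#' by its tissue:plasma partition coefficient (converted to blood terms via
#' the blood:plasma ratio).  Renal elimination is glomerular filtration of
#' unbound drug from arterial plasma, debited from the kidney compartment.
#' Doses enter venous blood; the reported plasma concentration is arterial
#' blood concentration divided by the blood:plasma ratio, i.e. the
#' concentration a sample drawn away from the infusion site sees.
#'
#' @param drug A [gentamicin()] parameter set.
#' @param physiology A [reference_dog()] physiology (possibly staged through
#'   [apply_renal_stage()]).
#' @return An object of class `pbpk_model` with elements `drug`,
#'   `physiology`, `kp` (partition coefficients) and `cl` (clearances).
#' @seealso [simulate_profile()], [pbpk_fit()]
#' @export
#' @examples
#' m <- pbpk_model()
#' coef(m)["reference_plasma_clearance"]
pbpk_model <- function(drug = gentamicin(), physiology = reference_dog()) {
  validate_drug_params(drug)
  stopifnot(inherits(physiology, "dog_physiology"))
  structure(
    list(drug = drug, physiology = physiology,
         kp = partition_coefficients(drug, physiology),
         cl = clearances(drug, physiology)),
    class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("Whole-body PK model (perfusion-limited, 7 compartments)\n")
  print(x$physiology)
  cat(sprintf("  renal CL %.3f L/h, unspecific CL %.3f L/h, Vss %.3f L/kg\n",
              x$cl$renal, x$cl$unspecific, vss_per_kg(x)))
  invisible(x)
}

#' @export
coef.pbpk_model <- function(object, ...) {
  d <- object$drug
  c(reference_plasma_clearance = d$reference_plasma_clearance,
    kp_scale = d$kp_scale, cl_unspecific = d$cl_unspecific,
    fu = d$fu, blood_plasma_ratio = d$blood_plasma_ratio,
    gfr = object$physiology$gfr)
}

#' @export
summary.pbpk_model <- function(object, ...) {
  out <- list(model = object,
              kp = object$kp,
              cl_total_per_kg = object$cl$total / object$physiology$weight,
              vss_per_kg = vss_per_kg(object),
              reference_consistency =
                check_clearance_consistency(object, error = FALSE))
  class(out) <- "summary.pbpk_model"
  out
}

#' @export
print.summary.pbpk_model <- function(x, ...) {
  print(x$model)
  cat("  partition coefficients:\n")
  print(round(x$kp, 4))
  cat(sprintf("  total CL %.4f L/h/kg vs reference %.4f L/h/kg (%s)\n",
              x$cl_total_per_kg,
              x$model$drug$reference_plasma_clearance,
              if (x$reference_consistency) "within 10%" else "OUTSIDE 10%"))
  invisible(x)
}

# Steady-state volume of distribution, L/kg, referenced to plasma.
vss_per_kg <- function(model) {
  org <- model$physiology$organs
  vb <- sum(org$volume_per_kg[org$organ %in% c("arterial_blood",
                                               "venous_blood")])
  vt <- org$volume_per_kg[match(.tissue_names, org$organ)]
  vb * model$drug$blood_plasma_ratio + sum(vt * model$kp)
}

#' Check total clearance against the reference plasma clearance
#'
#' For the healthy reference dog, simulated total plasma clearance
#' (fu x GFR + unspecific) must agree with the drug's reference plasma
#' clearance within 10%.
#'
#' @param model A [pbpk_model()].
#' @param tol Relative tolerance (default 0.1).
#' @param error If `TRUE`, fail with an error instead of returning `FALSE`.
#' @return Logical, invisibly `TRUE` when consistent.
#' @export
check_clearance_consistency <- function(model, tol = 0.1, error = TRUE) {
  got <- model$cl$total / model$physiology$weight
  want <- model$drug$reference_plasma_clearance
  ok <- abs(got - want) <= tol * want
  if (!ok && error)
    stop(sprintf("total plasma clearance %.4f L/h/kg deviates from the reference %.4f L/h/kg by more than %.0f%%",
                 got, want, 100 * tol))
  invisible(ok)
}

# Parameter vector for the compiled derivative (see src/pbpk.c).
pbpk_parms <- function(model, rate_in = 0) {
  org <- model$physiology$organs
  V <- org$volume[match(.organ_names, org$organ)]
  Q <- org$flow[match(.tissue_names, org$organ)]
  qco <- org$flow[org$organ == "arterial_blood"]
  c(V, Q, qco, model$kp, model$drug$blood_plasma_ratio,
    model$cl$renal, model$cl$unspecific, rate_in)
}

#' Default simulation output grid for a regimen
#'
#' 0.02-h steps during the first hour after each dose and 0.25-h steps
#' elsewhere, always including the dose times, the end-of-infusion times
#' (where the peak occurs), the 24-h marks used by the exposure windows and
#' the end of the regimen.
#'
#' @param regimen A [dose_regimen()].
#' @return Strictly increasing numeric vector of times in hours, from 0 to
#'   `n_doses * interval_h`.
#' @export
default_time_grid <- function(regimen) {
  horizon <- regimen$n_doses * regimen$interval_h
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval_h
  g <- c(seq(0, horizon, by = 0.25),
         unlist(lapply(dose_times, function(t0)
           seq(t0, min(t0 + 1, horizon), by = 0.02))),
         dose_times + regimen$infusion_h,
         seq(0, horizon, by = 24), horizon)
  sort(unique(round(g, 10)))
}

#' Simulate a concentration profile
#'
#' Integrates the whole-body mass balances over the full regimen with the
#' stiff-capable `lsoda` integrator (relative tolerance 1e-8, absolute
#' tolerance 1e-10), restarting the integration at every dose event.
#'
#' @param model A [pbpk_model()].
#' @param regimen A [dose_regimen()].
#' @param times Optional output grid (hours); must start at 0 and cover the
#'   regimen.  Defaults to [default_time_grid()].  Dose-event times (dose
#'   starts and infusion ends) are always part of the output; at a bolus
#'   dose time the recorded value is the pre-dose trough.
#' @return An object of class `concentration_profile`: a list with `time`
#'   (h), `conc` (plasma concentration, ug/mL), `amounts` (matrix of organ
#'   amounts, mg), `eliminated` (cumulative mg), `administered` (cumulative
#'   dosed mg at each time), plus the regimen and the dose in mg.
#' @export
#' @examples
#' prof <- simulate_profile(pbpk_model(), dose_regimen(2, n_doses = 1))
#' max(prof$conc)
simulate_profile <- function(model, regimen, times = NULL) {
  stopifnot(inherits(model, "pbpk_model"), inherits(regimen, "dose_regimen"))
  if (is.null(times)) times <- default_time_grid(regimen)
  horizon <- regimen$n_doses * regimen$interval_h
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing and start at 0")
  if (max(times) > horizon + 1e-9)
    stop("'times' must not extend beyond the regimen (",
         horizon, " h)")
  wt <- model$physiology$weight
  dose <- regimen$dose_per_kg * wt
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval_h

  y <- stats::setNames(numeric(8), c(.organ_names, "eliminated"))
  out_t <- numeric(0); out_y <- NULL; out_adm <- numeric(0)
  run_segment <- function(y, t0, t1, rate) {
    seg <- times[times > t0 + 1e-12 & times < t1 - 1e-12]
    tt <- unique(c(t0, seg, t1))
    o <- deSolve::ode(y, tt, func = "pbpk_derivs", parms =
                        pbpk_parms(model, rate),
                      dllname = "gentadog", initfunc = "pbpk_init",
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
    if (attr(o, "istate")[1] < 0)
      stop("ODE solver failed to converge (istate ",
           attr(o, "istate")[1], ") in segment [", t0, ", ", t1, "] h")
    o
  }
  collect <- function(o, adm) {
    keep <- if (length(out_t)) seq_len(nrow(o))[-1] else seq_len(nrow(o))
    out_t <<- c(out_t, o[keep, 1])
    out_y <<- rbind(out_y, o[keep, -1])
    out_adm <<- c(out_adm, adm[keep])
  }
  for (k in seq_len(regimen$n_doses)) {
    t0 <- dose_times[k]
    t_next <- if (k < regimen$n_doses) dose_times[k + 1] else horizon
    if (regimen$infusion_h > 0 && dose > 0) {
      t1 <- t0 + regimen$infusion_h
      o <- run_segment(y, t0, t1, dose / regimen$infusion_h)
      y <- o[nrow(o), -1]
      collect(o, (k - 1) * dose +
                (o[, 1] - t0) / regimen$infusion_h * dose)
      t0 <- t1
    } else {
      y[["venous_blood"]] <- y[["venous_blood"]] + dose
    }
    o <- run_segment(y, t0, t_next, 0)
    y <- o[nrow(o), -1]
    collect(o, rep(k * dose, nrow(o)))
  }
  amounts <- out_y[, seq_along(.organ_names), drop = FALSE]
  colnames(amounts) <- .organ_names
  if (any(amounts < -1e-6 * max(dose, 1)))
    stop("negative compartment amounts: integration unstable")
  amounts[amounts < 0] <- 0
  conc <- amounts[, "arterial_blood"] /
    model$physiology$organs$volume[
      model$physiology$organs$organ == "arterial_blood"] /
    model$drug$blood_plasma_ratio
  structure(list(time = out_t, conc = as.numeric(conc), amounts = amounts,
                 eliminated = as.numeric(out_y[, 8]),
                 administered = out_adm,
                 regimen = regimen, dose_mg = dose,
                 weight = wt),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile: %d time points over %.1f h, ",
              length(x$time), max(x$time)))
  cat(sprintf("Cmax %.3g ug/mL\n", max(x$conc)))
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(time_h = x$time, plasma_conc_ug_ml = x$conc)
}

#' @export
plot.concentration_profile <- function(x, log = "y", ...) {
  conc <- x$conc
  if (grepl("y", log)) conc <- pmax(conc, 1e-6)
  plot(x$time, conc, type = "l", log = log,
       xlab = "Time (h)", ylab = "Plasma concentration (µg/mL)", ...)
  invisible(x)
}

#' Predicted plasma concentrations
#'
#' @param object A [pbpk_model()].
#' @param regimen A [dose_regimen()].
#' @param times Optional times (hours) at which concentrations are wanted;
#'   they are added to the solver output grid, so no interpolation is
#'   involved.
#' @param ... Unused.
#' @return A data frame with columns `time_h` and `plasma_conc_ug_ml`.
#' @export
predict.pbpk_model <- function(object, regimen = dose_regimen(2),
                               times = NULL, ...) {
  grid <- default_time_grid(regimen)
  if (!is.null(times)) {
    if (any(times < 0 | times > regimen$n_doses * regimen$interval_h))
      stop("'times' must lie within the regimen")
    grid <- sort(unique(c(grid, times)))
  }
  prof <- simulate_profile(object, regimen, grid)
  df <- as.data.frame(prof)
  if (!is.null(times))
    df <- df[vapply(df$time_h, function(t) any(abs(t - times) < 1e-9),
                    logical(1)), , drop = FALSE]
  df
}

#' Simulate exposure in a virtual population
#'
#' Draws `nsim` virtual dogs at the model's renal stage and returns their
#' individual exposure metrics under `regimen`.
#'
#' @param object A [pbpk_model()]; its physiology's `stage` and the stage's
#'   GFR set the population mean.
#' @param nsim Number of virtual individuals.
#' @param seed Integer seed for the population draw.
#' @param regimen A [dose_regimen()].
#' @param weight_range,cv_gfr Population settings, see [sample_population()].
#' @param ... Unused.
#' @return A data frame of per-individual exposure metrics (see
#'   [exposure_metrics()]).
#' @export
simulate.pbpk_model <- function(object, nsim = 100, seed = 1,
                                regimen = dose_regimen(2),
                                weight_range = c(8, 12), cv_gfr = 0.15, ...) {
  pop <- sample_population(nsim, weight_range = weight_range,
                           stage = object$physiology$stage,
                           cv_gfr = cv_gfr, seed = seed,
                           gfr_healthy = object$physiology$gfr /
                             resolve_stage(object$physiology$stage)$gfr_fraction)
  population_exposure(pop, regimen, drug = object$drug)
}
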