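#' Fit drug parameters to observed concentration-time data
#'
#' Parameter identification by least squares on log concentrations: the
#' whole-body model is simulated under each study's own regimen and the sum
#' of squared log-scale residuals over all points and studies is minimised.
#' The free parameters may be any subset of `reference_plasma_clearance`
#' (the renal reference clearance; the healthy training subjects' GFR is
#' implied by it through the fraction unbound), `kp_scale` (global tissue
#' partitioning) and `cl_unspecific` (non-renal clearance).  Optimisation
#' is deterministic from a fixed starting point: golden-section/Brent search
#' for one free parameter, Nelder-Mead on the log scale otherwise.
#'
#' @param observed Observed data in the [read_observed_csv()] dialect;
#'   concentrations must be positive (log residuals).
#' @param free Character vector of free parameter names.
#' @param drug Starting drug parameters.
#' @param table Organ composition table.
#' @return An object of class `pbpk_fit` with the fitted `drug`, the
#'   implied healthy `model`, the objective value and per-point residuals.
#' @export
#' @examples
#' \donttest{
#' dat <- generate_observed_dataset(synthetic_design(noise_cv = 0,
#'                                                   n_subjects = 1))
#' fit <- pbpk_fit(dat, free = "reference_plasma_clearance")
#' coef(fit)
#' }
pbpk_fit <- function(observed, free = "reference_plasma_clearance",
                     drug = gentamicin(), table = dog_physiology_table()) {
  obs <- validate_observed(observed)
  if (!nrow(obs)) stop("empty observed dataset")
  allowed <- c("reference_plasma_clearance", "kp_scale", "cl_unspecific")
  if (!length(free) || !all(free %in% allowed))
    stop("'free' must be a non-empty subset of: ",
         paste(allowed, collapse = ", "))
  if (any(obs$conc_ug_ml <= 0))
    stop("observed concentrations must be positive for log-scale fitting")

  studies <- split(obs, obs$study_id)
  study_regimens <- lapply(studies, function(s) {
    s <- s[order(s$time_h), ]
    dose_regimen(s$dose_mg_kg[1], interval_h = max(s$time_h) + 0.25,
                 n_doses = 1,
                 infusion_h = if (s$route[1] == "infusion")
                   s$infusion_h[1] else 0)
  })

  build_model <- function(d) {
    gfr <- d$reference_plasma_clearance / d$fu * 1000 / 60
    pbpk_model(d, reference_dog(gfr = gfr, table = table))
  }
  predict_study <- function(model, i) {
    s <- studies[[i]][order(studies[[i]]$time_h), ]
    predict(model, study_regimens[[i]], times = s$time_h)$plasma_conc_ug_ml
  }
  objective_for <- function(d) {
    model <- build_model(d)
    sum(vapply(seq_along(studies), function(i) {
      s <- studies[[i]][order(studies[[i]]$time_h), ]
      pred <- predict_study(model, i)
      if (any(pred <= 0)) return(Inf)
      sum((log(pred) - log(s$conc_ug_ml))^2)
    }, numeric(1)))
  }
  start <- vapply(free, function(p) {
    v <- drug[[p]]
    if (p == "cl_unspecific" && v <= 0) 0.01 else v
  }, numeric(1))
  apply_theta <- function(theta) {
    d <- drug
    for (j in seq_along(free)) d[[free[j]]] <- exp(theta[j])
    d
  }
  fn <- function(theta) {
    val <- objective_for(apply_theta(theta))
    if (!is.finite(val)) 1e10 else val
  }
  theta0 <- log(start)
  if (length(free) == 1L) {
    opt <- stats::optimize(fn, interval = theta0 + c(-log(10), log(10)),
                           tol = 1e-8)
    theta_hat <- opt$minimum; value <- opt$objective; convergence <- 0L
  } else {
    opt <- stats::optim(theta0, fn, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    theta_hat <- opt$par; value <- opt$value; convergence <- opt$convergence
  }
  if (!is.finite(value))
    stop("non-finite objective at the optimum: fit failed")
  fitted_drug <- apply_theta(theta_hat)
  model <- build_model(fitted_drug)
  resid <- do.call(rbind, lapply(seq_along(studies), function(i) {
    s <- studies[[i]][order(studies[[i]]$time_h), ]
    pred <- predict_study(model, i)
    data.frame(study_id = s$study_id, time_h = s$time_h,
               observed = s$conc_ug_ml, predicted = pred,
               log_residual = log(s$conc_ug_ml) - log(pred))
  }))
  rownames(resid) <- NULL
  structure(list(drug = fitted_drug, model = model, free = free,
                 objective = value, convergence = convergence,
                 residuals = resid, n_points = nrow(obs),
                 n_studies = length(studies)),
            class = "pbpk_fit")
}

#' @export
coef.pbpk_fit <- function(object, ...) {
  vapply(object$free, function(p) object$drug[[p]], numeric(1))
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat("Whole-body PK model fit (log-scale least squares)\n")
  cat(sprintf("  %d studies, %d points; objective %.6g; convergence %d\n",
              x$n_studies, x$n_points, x$objective, x$convergence))
  cat("  fitted parameters:\n")
  print(coef(x))
  invisible(x)
}

#' @export
summary.pbpk_fit <- function(object, ...) {
  r <- object$residuals$log_residual
  out <- list(fit = object,
              rse = sqrt(mean(r^2)),
              residual_range = range(r))
  class(out) <- "summary.pbpk_fit"
  out
}

#' @export
print.summary.pbpk_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  log-residual RMSE %.4f, range [%.3f, %.3f]\n",
              x$rse, x$residual_range[1], x$residual_range[2]))
  invisible(x)
}

#' @export
residuals.pbpk_fit <- function(object, ...) {
  object$residuals
}

#' @export
predict.pbpk_fit <- function(object, regimen = dose_regimen(2),
                             times = NULL, ...) {
  predict(object$model, regimen, times = times, ...)
}

#' @export
plot.pbpk_fit <- function(x, ...) {
  r <- x$residuals
  lim <- range(c(r$observed, r$predicted))
  plot(r$observed, r$predicted, log = "xy", xlim = lim, ylim = lim,
       xlab = "Observed (µg/mL)", ylab = "Predicted (µg/mL)", ...)
  graphics::abline(0, 1)
  graphics::abline(log10(2), 1, lty = 2)
  graphics::abline(-log10(2), 1, lty = 2)
  invisible(x)
}
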