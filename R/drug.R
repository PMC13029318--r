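#' Gentamicin drug parameters
#'
#' Physicochemical and ADME constants of gentamicin together with the two
#' calibration scalars of the distribution model.  Gentamicin is a polar
#' polybasic aminoglycoside (logP -1.6); the single acidic pKa carried here
#' (12.55) means the molecule is treated as fully ionised at physiological
#' pH, so no pH-partitioning term enters the tissue model — distribution is
#' essentially extracellular, which is why the calibrated steady-state
#' volume of distribution is only about 0.2 L/kg.
#'
#' @param molecular_weight g/mol.
#' @param pka_acid Acid dissociation constant (metadata; no pathway into the
#'   kinetics, see Details).
#' @param logp Octanol:water log partition coefficient.
#' @param fu Fraction unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio Blood:plasma concentration ratio.
#' @param reference_plasma_clearance Total plasma clearance of the healthy
#'   reference dog, L/h/kg.
#' @param kp_scale Global multiplier on the composition-based tissue:plasma
#'   partition coefficients.  The default 0.22 is a calibration constant
#'   chosen so that Vss is about 0.20 L/kg (extracellular distribution);
#'   see [partition_coefficients()].
#' @param k_protein Protein-binding coefficient of the composition rule.
#' @param cl_unspecific Unspecific (non-renal) plasma clearance, L/h/kg.
#'   Gentamicin is eliminated essentially unchanged by glomerular
#'   filtration, so the default is 0; kept as a free calibration parameter
#'   for fitting.
#' @param kp_overrides Named list of per-organ Kp values that bypass the
#'   composition rule, e.g. `list(muscle = 0.3)`.
#' @return An object of class `drug_params`.
#' @export
#' @examples
#' gentamicin()
gentamicin <- function(molecular_weight = 477.6,
                       pka_acid = 12.55,
                       logp = -1.6,
                       fu = 0.85,
                       blood_plasma_ratio = 0.82,
                       reference_plasma_clearance = 0.17,
                       kp_scale = 0.22,
                       k_protein = 0.1,
                       cl_unspecific = 0,
                       kp_overrides = list()) {
  drug <- structure(
    list(molecular_weight = molecular_weight, pka_acid = pka_acid,
         logp = logp, fu = fu, blood_plasma_ratio = blood_plasma_ratio,
         reference_plasma_clearance = reference_plasma_clearance,
         kp_scale = kp_scale, k_protein = k_protein,
         cl_unspecific = cl_unspecific, kp_overrides = kp_overrides),
    class = "drug_params")
  validate_drug_params(drug)
}

validate_drug_params <- function(drug) {
  with(drug, {
    if (!is.finite(molecular_weight) || molecular_weight <= 0)
      stop("molecular_weight must be positive")
    if (!is.finite(fu) || fu <= 0 || fu > 1)
      stop("fu must lie in (0, 1]")
    if (!is.finite(blood_plasma_ratio) || blood_plasma_ratio <= 0)
      stop("blood_plasma_ratio must be positive")
    if (!is.finite(kp_scale) || kp_scale <= 0)
      stop("kp_scale must be positive")
    if (!is.finite(cl_unspecific) || cl_unspecific < 0)
      stop("cl_unspecific must be non-negative")
    if (!is.finite(reference_plasma_clearance) ||
        reference_plasma_clearance <= 0)
      stop("reference_plasma_clearance must be positive")
  })
  ov <- drug$kp_overrides
  if (length(ov)) {
    if (is.null(names(ov)) || !all(names(ov) %in% .tissue_names))
      stop("kp_overrides must be named after tissues: ",
           paste(.tissue_names, collapse = ", "))
    if (any(unlist(ov) <= 0)) stop("kp_overrides must be positive")
  }
  drug
}

#' @export
print.drug_params <- function(x, ...) {
  cat("Drug parameters\n")
  cat(sprintf("  MW %.1f g/mol, logP %.2f, pKa(acid) %.2f\n",
              x$molecular_weight, x$logp, x$pka_acid))
  cat(sprintf("  fu %.2f, B:P %.2f, reference CL %.3f L/h/kg\n",
              x$fu, x$blood_plasma_ratio, x$reference_plasma_clearance))
  cat(sprintf("  kp_scale %.3f, k_protein %.2f, unspecific CL %.3f L/h/kg\n",
              x$kp_scale, x$k_protein, x$cl_unspecific))
  if (length(x$kp_overrides))
    cat("  Kp overrides:",
        paste(names(x$kp_overrides), unlist(x$kp_overrides),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Composition-based tissue:plasma partition coefficients
#'
#' For each tissue, `Kp = kp_scale * (f_water + 10^logp * f_lipid +
#' k_protein * f_protein)`: drug dissolves fully in tissue water, partitions
#' into neutral lipid according to its lipophilicity, and binds tissue
#' protein with a fixed affinity.  Organs listed in `drug$kp_overrides`
#' return the override unchanged.
#'
#' @param drug A [gentamicin()] parameter set.
#' @param phys A [reference_dog()] physiology.
#' @return Named numeric vector of Kp values, one per tissue compartment.
#' @export
#' @examples
#' partition_coefficients(gentamicin(), reference_dog())
partition_coefficients <- function(drug, phys) {
  validate_drug_params(drug)
  stopifnot(inherits(phys, "dog_physiology"))
  tis <- phys$organs[match(.tissue_names, phys$organs$organ), ]
  if (any(is.na(tis$f_water) | is.na(tis$f_lipid) | is.na(tis$f_protein)))
    stop("tissue composition fractions are missing")
  klip <- 10^drug$logp
  kp <- drug$kp_scale *
    (tis$f_water + klip * tis$f_lipid + drug$k_protein * tis$f_protein)
  names(kp) <- .tissue_names
  for (org in names(drug$kp_overrides))
    kp[[org]] <- drug$kp_overrides[[org]]
  if (any(kp <= 0)) stop("partition coefficients must be positive")
  kp
}

#' Renal and unspecific plasma clearance
#'
#' Gentamicin is cleared by glomerular filtration of unbound drug:
#' `CL_renal = fu * GFR * weight`, converted from mL/min to L/h.  The
#' unspecific clearance is `cl_unspecific * weight` (0 by default).
#'
#' @param drug A [gentamicin()] parameter set.
#' @param phys A [reference_dog()] physiology.
#' @return List with elements `renal`, `unspecific` and `total`, all in L/h.
#' @export
#' @examples
#' clearances(gentamicin(), reference_dog())
clearances <- function(drug, phys) {
  validate_drug_params(drug)
  stopifnot(inherits(phys, "dog_physiology"))
  if (phys$gfr < 0) stop("gfr must be non-negative")
  renal <- drug$fu * phys$gfr * phys$weight * 60 / 1000
  unspecific <- drug$cl_unspecific * phys$weight
  list(renal = renal, unspecific = unspecific, total = renal + unspecific)
}
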