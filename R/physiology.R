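#' Canine organ composition table
#'
#' Reference organ volumes, blood flows and tissue composition for an adult
#' dog, expressed per kg body weight so that they scale linearly with weight.
#' The two blood rows carry total cardiac output in `flow_per_kg` (8.6 L/h/kg,
#' about 143 mL/min/kg); tissue rows carry the regional blood flow.  Tissue
#' mass fractions of water, neutral lipid and protein feed the
#' composition-based partition-coefficient rule (see
#' [partition_coefficients()]).  The organ set is deliberately compact:
#' muscle, adipose and kidney are kept explicit because systemic exposure is
#' most sensitive to them; the remaining viscera are pooled into `rest`.
#'
#' @return A data frame with columns `organ`, `volume_per_kg` (L/kg),
#'   `flow_per_kg` (L/h/kg), `f_water`, `f_lipid`, `f_protein`.
#' @export
#' @examples
#' dog_physiology_table()
dog_physiology_table <- function() {
  path <- system.file("extdata", "dog_physiology.csv", package = "gentadog",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_physiology_table(tab)
  tab
}

.organ_names <- c("arterial_blood", "venous_blood", "muscle", "adipose",
                  "kidney", "liver", "rest")
.tissue_names <- c("muscle", "adipose", "kidney", "liver", "rest")

validate_physiology_table <- function(tab) {
  need <- c("organ", "volume_per_kg", "flow_per_kg",
            "f_water", "f_lipid", "f_protein")
  if (!all(need %in% names(tab)))
    stop("physiology table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(tab$organ, .organ_names))
    stop("physiology table must describe exactly the organs: ",
         paste(.organ_names, collapse = ", "))
  if (any(tab$volume_per_kg <= 0))
    stop("organ volumes must be positive")
  if (any(tab$flow_per_kg <= 0))
    stop("organ flows must be positive")
  frac <- tab$f_water + tab$f_lipid + tab$f_protein
  if (any(tab$f_water < 0 | tab$f_lipid < 0 | tab$f_protein < 0 | frac > 1))
    stop("composition fractions must be non-negative and sum to at most 1")
  co <- tab$flow_per_kg[tab$organ == "arterial_blood"]
  tis <- tab$flow_per_kg[tab$organ %in% .tissue_names]
  if (abs(sum(tis) - co) > 1e-9)
    stop("tissue blood flows must sum to cardiac output (within 1e-9)")
  invisible(tab)
}

#' Build the physiology of one virtual dog
#'
#' Scales the per-kg organ table to an individual body weight.  The default
#' weight of 10.5 kg is the reference beagle; the default glomerular
#' filtration rate of 3.33 mL/min/kg corresponds, through the fraction
#' unbound (0.85), to the reference plasma clearance of gentamicin,
#' 0.17 L/h/kg.
#'
#' @param weight Body weight in kg (positive scalar).
#' @param gfr Glomerular filtration rate, mL/min/kg.
#' @param hematocrit Haematocrit fraction (only carried as metadata; the
#'   blood:plasma partitioning of the drug is governed by the drug's
#'   blood:plasma ratio).
#' @param table Organ composition table in the format of
#'   [dog_physiology_table()].
#' @return An object of class `dog_physiology`: a list with elements
#'   `weight` (kg), `gfr` (mL/min/kg), `hematocrit`, `stage` (renal-stage
#'   label, `"healthy"` until altered), and `organs`, a data frame with
#'   absolute `volume` (L) and `flow` (L/h) columns alongside the
#'   composition fractions.
#' @export
#' @examples
#' ref <- reference_dog()
#' ref$weight * ref$gfr  # total GFR, mL/min
reference_dog <- function(weight = 10.5, gfr = 3.33, hematocrit = 0.45,
                          table = dog_physiology_table()) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0)
    stop("'weight' must be a positive number")
  if (!is.numeric(gfr) || length(gfr) != 1L || !is.finite(gfr) || gfr < 0)
    stop("'gfr' must be a non-negative number")
  validate_physiology_table(table)
  organs <- table
  organs$volume <- organs$volume_per_kg * weight
  organs$flow <- organs$flow_per_kg * weight
  structure(
    list(weight = weight, gfr = gfr, hematocrit = hematocrit,
         stage = "healthy", organs = organs),
    class = "dog_physiology")
}

#' @export
print.dog_physiology <- function(x, ...) {
  cat(sprintf("Virtual dog: %.2f kg, GFR %.2f mL/min/kg (stage: %s)\n",
              x$weight, x$gfr, x$stage))
  cat(sprintf("  blood volume %.3f L, cardiac output %.1f L/h\n",
              sum(x$organs$volume[x$organs$organ %in%
                                    c("arterial_blood", "venous_blood")]),
              x$organs$flow[x$organs$organ == "arterial_blood"]))
  invisible(x)
}

#' Renal-function stages
#'
#' The six virtual populations are stratified by clinical biomarkers of
#' chronic kidney disease (microalbuminuria, urinary protein:creatinine
#' ratio, serum creatinine), each mapped to a fraction of healthy GFR.  The
#' biomarker-to-GFR mapping is a set of package calibration constants, not
#' literature measurements: the fractions were fixed once so that downstream
#' dose-optimisation and risk tables preserve the clinical ordering of the
#' stages.  They can be overridden wherever a `stage` argument is accepted.
#'
#' @return A data frame with columns `label` and `gfr_fraction`.
#' @export
renal_stages <- function() {
  data.frame(
    label = c("healthy", "microalbuminuria", "upc_ge_2",
              "scr_ge_1_2", "scr_ge_2_4", "scr_ge_5"),
    gfr_fraction = c(1.0, 0.80, 0.50, 0.40, 0.20, 0.10),
    stringsAsFactors = FALSE)
}

resolve_stage <- function(stage) {
  stages <- renal_stages()
  if (is.character(stage) && length(stage) == 1L) {
    i <- match(stage, stages$label)
    if (is.na(i))
      stop("unknown renal stage '", stage, "'; known stages: ",
           paste(stages$label, collapse = ", "))
    return(stages[i, ])
  }
  if (is.data.frame(stage) && all(c("label", "gfr_fraction") %in% names(stage)) &&
      nrow(stage) == 1L) {
    if (!is.finite(stage$gfr_fraction) || stage$gfr_fraction <= 0 ||
        stage$gfr_fraction > 1)
      stop("stage gfr_fraction must lie in (0, 1]")
    return(stage)
  }
  stop("'stage' must be a stage label or a one-row data frame with ",
       "columns label and gfr_fraction")
}

#' Apply a renal-function stage to a dog
#'
#' Returns the same physiology with GFR multiplied by the stage's fraction
#' of healthy GFR; nothing else changes.
#'
#' @param phys A [reference_dog()] object.
#' @param stage A stage label (see [renal_stages()]) or a one-row data frame
#'   with columns `label` and `gfr_fraction`.
#' @return A `dog_physiology` object.
#' @export
#' @examples
#' apply_renal_stage(reference_dog(), "scr_ge_5")$gfr
apply_renal_stage <- function(phys, stage) {
  stopifnot(inherits(phys, "dog_physiology"))
  st <- resolve_stage(stage)
  phys$gfr <- phys$gfr * st$gfr_fraction
  phys$stage <- st$label
  phys
}

#' Sample a virtual dog population
#'
#' Draws `n` individuals with body weight uniform on `weight_range` and GFR
#' lognormal around the stage mean (healthy GFR times the stage's
#' `gfr_fraction`) with coefficient of variation `cv_gfr`.  The lognormal is
#' parameterised so that its arithmetic mean equals the stage mean.  The
#' draw is fully determined by `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param n Number of individuals (>= 1).
#' @param weight_range Length-2 numeric, min and max body weight in kg.
#' @param stage Renal stage label or one-row stage data frame.
#' @param cv_gfr Lognormal coefficient of variation of individual GFR
#'   (>= 0; 0 gives every individual the stage mean).
#' @param seed Integer seed.
#' @param gfr_healthy Healthy-population mean GFR, mL/min/kg.
#' @return A data frame of class `dog_population` with columns
#'   `individual_id`, `weight_kg`, `gfr_ml_min_kg`, `stage`.
#' @export
#' @examples
#' pop <- sample_population(5, seed = 1)
#' range(pop$weight_kg)
sample_population <- function(n, weight_range = c(8, 12), stage = "healthy",
                              cv_gfr = 0.15, seed = 1, gfr_healthy = 3.33) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be at least 1")
  n <- as.integer(n)
  if (length(weight_range) != 2L || any(!is.finite(weight_range)) ||
      weight_range[1] <= 0 || weight_range[1] > weight_range[2])
    stop("'weight_range' must satisfy 0 < min <= max")
  if (!is.numeric(cv_gfr) || cv_gfr < 0)
    stop("'cv_gfr' must be non-negative")
  st <- resolve_stage(stage)
  mu_gfr <- gfr_healthy * st$gfr_fraction
  pop <- with_seed(seed, {
    w <- stats::runif(n, weight_range[1], weight_range[2])
    if (cv_gfr > 0) {
      sdlog <- sqrt(log(1 + cv_gfr^2))
      g <- stats::rlnorm(n, meanlog = log(mu_gfr) - sdlog^2 / 2, sdlog = sdlog)
    } else {
      g <- rep(mu_gfr, n)
    }
    data.frame(individual_id = seq_len(n), weight_kg = w,
               gfr_ml_min_kg = g, stage = st$label,
               stringsAsFactors = FALSE)
  })
  class(pop) <- c("dog_population", "data.frame")
  pop
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a population to CSV
#'
#' @param pop A [sample_population()] data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  utils::write.csv(
    pop[, c("individual_id", "weight_kg", "gfr_ml_min_kg", "stage")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
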