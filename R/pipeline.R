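default_run_config <- function() {
  list(
    drug = list(),  # overrides on gentamicin() fields
    population = list(n = 2000, weight_range = c(8, 12),
                      stages = renal_stages()$label, cv_gfr = 0.15,
                      seed = 1, gfr_healthy = 3.33),
    regimen = list(doses = c(2, 4, 6, 8, 10), intervals = 24,
                   n_doses = 3, infusion_h = 0.5),
    targets = list(indices = c("cmax_over_mic", "auc24_over_mic"),
                   auc_thresholds = c(50, 110), cmax_threshold = 10,
                   mic_grid = .default_mic_grid,
                   pta_threshold = 90, risk_threshold = 10))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, applies the package defaults for anything
#' not given, and rejects unknown keys.  An empty (or absent) file yields
#' the full default study: doses 2-10 mg/kg q24h for three days, MIC grid
#' 0.25-8 ug/mL, six renal stages, 2000 individuals per stage.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
#' @examples
#' cfg <- load_run_config(NULL)
#' cfg$regimen$doses
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    # keep single-letter keys like "n" as strings (YAML 1.1 would read
    # them as booleans); no configuration field is logical
    user <- yaml::read_yaml(path, handlers = list("bool#no" = identity,
                                                  "bool#yes" = identity))
    if (is.null(user)) user <- list()
    for (blk in names(user)) {
      if (!blk %in% names(cfg))
        stop("unknown configuration block '", blk, "'")
      if (!is.list(user[[blk]]))
        stop("configuration block '", blk, "' must be a mapping")
      for (key in names(user[[blk]])) {
        if (blk == "drug") {
          if (!key %in% names(gentamicin()))
            stop("unknown drug parameter '", key, "'")
        } else if (!key %in% names(cfg[[blk]])) {
          stop("unknown configuration key '", blk, ".", key, "'")
        }
        cfg[[blk]][[key]] <- user[[blk]][[key]]
      }
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  # YAML sequences of mixed integer/real values parse as lists
  num <- function(x) as.numeric(unlist(x))
  cfg$population$weight_range <- num(cfg$population$weight_range)
  cfg$population$n <- num(cfg$population$n)
  cfg$population$cv_gfr <- num(cfg$population$cv_gfr)
  cfg$population$seed <- as.integer(num(cfg$population$seed))
  cfg$population$gfr_healthy <- num(cfg$population$gfr_healthy)
  cfg$population$stages <- unlist(cfg$population$stages)
  cfg$regimen <- lapply(cfg$regimen, num)
  for (k in c("auc_thresholds", "cmax_threshold", "mic_grid",
              "pta_threshold", "risk_threshold"))
    cfg$targets[[k]] <- num(cfg$targets[[k]])
  cfg$targets$indices <- unlist(cfg$targets$indices)
  p <- cfg$population
  if (p$n < 1) stop("population.n must be at least 1")
  if (length(p$weight_range) != 2 || p$weight_range[1] <= 0 ||
      p$weight_range[1] > p$weight_range[2])
    stop("population.weight_range must satisfy 0 < min <= max")
  lapply(p$stages, resolve_stage)
  r <- cfg$regimen
  if (any(r$doses < 0)) stop("regimen.doses must be non-negative")
  if (any(r$intervals <= 0)) stop("regimen.intervals must be positive")
  tg <- cfg$targets
  if (any(!tg$indices %in% c("cmax_over_mic", "auc24_over_mic")))
    stop("targets.indices must be cmax_over_mic and/or auc24_over_mic")
  if (any(tg$mic_grid <= 0)) stop("targets.mic_grid must be positive")
  drug <- do.call(gentamicin, cfg$drug)  # validates overrides
  structure(cfg, drug_object = drug, class = "run_config")
}

#' Run the population dosing study end to end
#'
#' Samples one virtual population per renal stage, simulates every
#' dose/interval regimen, computes PTA across the MIC grid for the
#' configured PK/PD indices, the nephrotoxicity risks, and the qualifying
#' regimen recommendations, and writes everything to `out_dir`:
#' `population.csv`, `pta.csv`, `toxicity.csv`, `recommendations.json`,
#' the effective configuration (`config_echo.yaml`) and a plain-text run
#' log.  Stage s of the run uses sub-seed `seed + 1000 * s`, so the whole
#' bundle is reproducible from the configuration alone.
#'
#' @param config A [load_run_config()] result (or `NULL` for defaults).
#' @param out_dir Output directory, created if needed.
#' @param seed Overrides `population.seed` when not `NULL`.
#' @param n Overrides `population.n` when not `NULL`.
#' @return Invisibly, a list with the pta, toxicity and recommendation
#'   tables and the per-stage exposure metrics.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(NULL, out_dir = tempfile(), n = 20)
#' head(out$pta)
#' }
run_pipeline <- function(config = NULL, out_dir = "gentadog-run",
                         seed = NULL, n = NULL) {
  if (is.null(config)) config <- load_run_config(NULL)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  if (!is.null(seed)) config$population$seed <- seed
  if (!is.null(n)) config$population$n <- n
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  drug <- attr(config, "drug_object")
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  t_start <- Sys.time()
  log_line("gentadog %s | seed %d | n %d per stage",
           as.character(utils::packageVersion("gentadog")),
           config$population$seed, config$population$n)

  stages <- config$population$stages
  metrics <- vector("list", 0)
  pops <- vector("list", 0)
  for (s in seq_along(stages)) {
    sub_seed <- config$population$seed + 1000L * s
    pop <- sample_population(
      config$population$n, weight_range = config$population$weight_range,
      stage = stages[s], cv_gfr = config$population$cv_gfr,
      seed = sub_seed, gfr_healthy = config$population$gfr_healthy)
    pops[[stages[s]]] <- pop
    for (iv in config$regimen$intervals) {
      m <- exposure_grid(pop, doses = config$regimen$doses,
                         interval_h = iv,
                         n_doses = config$regimen$n_doses,
                         infusion_h = config$regimen$infusion_h,
                         drug = drug)
      metrics[[length(metrics) + 1L]] <- m
    }
    log_line("stage %-18s sub-seed %-8d %d individuals, %d regimens",
             stages[s], sub_seed, nrow(pop),
             length(config$regimen$doses) *
               length(config$regimen$intervals))
  }
  metrics <- do.call(rbind, metrics)

  tg <- config$targets
  target_list <- list()
  if ("cmax_over_mic" %in% tg$indices)
    target_list <- c(target_list,
                     list(efficacy_target("cmax_over_mic",
                                          tg$cmax_threshold)))
  if ("auc24_over_mic" %in% tg$indices)
    target_list <- c(target_list, lapply(tg$auc_thresholds, function(th)
      efficacy_target("auc24_over_mic", th)))
  pta <- do.call(rbind, lapply(target_list, function(t)
    compute_pta(metrics, t, mic_grid = tg$mic_grid)))
  tox <- rbind(toxicity_risk(metrics, "cmin_ge_0_5"),
               toxicity_risk(metrics, "auc24_ge_700"))
  conservative <- pta[pta$index == "auc24_over_mic" &
                        pta$threshold == min(tg$auc_thresholds), ]
  rec <- recommend_regimen(conservative,
                           tox[tox$criterion == "cmin_ge_0_5", ],
                           pta_threshold = tg$pta_threshold,
                           risk_threshold = tg$risk_threshold)

  pop_all <- do.call(rbind, pops)
  write_population_csv(pop_all, file.path(out_dir, "population.csv"))
  write_table <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  write_table(pta, "pta.csv")
  write_table(tox, "toxicity.csv")
  rec_json <- lapply(split(rec, paste(rec$stage, rec$mic_ug_ml)), function(g)
    list(stage = g$stage[1], mic = g$mic_ug_ml[1],
         qualifying_regimens = lapply(seq_len(nrow(g)), function(i)
           list(dose_mg_kg = g$dose_mg_kg[i], interval_h = g$interval_h[i])),
         flagged_regimen = {
           f <- g[g$flagged, ]
           list(dose_mg_kg = f$dose_mg_kg[1], interval_h = f$interval_h[1])
         }))
  jsonlite::write_json(unname(rec_json),
                       file.path(out_dir, "recommendations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_echo.yaml"))
  log_line("pta rows %d | toxicity rows %d | recommendations %d | %.1f s",
           nrow(pta), nrow(tox), nrow(rec),
           as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(list(pta = pta, toxicity = tox, recommendations = rec,
                 metrics = metrics, config = config))
}
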