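# gentadog

Gentamicin remains a first-line bactericidal antibiotic for Gram-negative
infections in dogs, but it has a narrow therapeutic index: the same renal
filtration that clears it also accumulates it in the kidney, and dogs with
chronic kidney disease are simultaneously the patients who need effective
dosing most and tolerate overexposure least. `gentadog` is an R package for
veterinary pharmacometricians that simulates intravenous gentamicin with a
whole-body (physiologically based) pharmacokinetic model of the dog,
stratifies virtual populations by glomerular filtration rate (GFR), and
scores candidate regimens by probability of target attainment (PTA) and
nephrotoxicity risk, so that a dose and dosing interval can be matched to
the infecting organism's MIC and the patient's renal stage.

## The model

Each virtual dog is a perfusion-limited compartment system — arterial and
venous blood plus muscle, adipose, kidney, liver and pooled remaining
tissue — with mass balances

    dA_i/dt = Q_i (C_art − C_i · BP / Kp_i)

for each tissue *i* (amount *A*, regional blood flow *Q*, blood:plasma
ratio BP), tissue:plasma partition coefficients from a composition rule

    Kp_i = kp_scale · (f_water,i + 10^logP · f_lipid,i + k_protein · f_protein,i),

and renal elimination by glomerular filtration of unbound drug,
CL_renal = fu · GFR · weight, debited from the kidney compartment at the
arterial plasma concentration. Doses enter venous blood as boluses or
zero-order infusions; the system is integrated with a stiff-capable solver
(`deSolve::lsoda`, compiled right-hand side) with restarts at dose events.

On top of the simulator sit:

* **Virtual populations** — six renal stages (healthy, microalbuminuria,
  UPC ≥ 2, sCr ≥ 1.2 / 2.4 / 5 mg/dL) as fractions of healthy GFR, body
  weight uniform on 8–12 kg, lognormal between-dog GFR variability.
* **PK/PD scoring** — PTA for Cmax/MIC ≥ 10 and AUC24/MIC ≥ 50 or 110
  over a MIC grid (0.25–8 µg/mL); nephrotoxicity as the population
  fraction with AUC24 ≥ 700 mg·h/L or trough ≥ 0.5 µg/mL; minimal
  effective doses and regimens that are simultaneously effective
  (PTA ≥ 90%) and safe (risk ≤ 10%).
* **Parameter identification** — least squares on log concentrations
  against observed series (`pbpk_fit()`), with the standard `coef`,
  `residuals`, `predict`, `plot` methods.
* **Model qualification** — geometric mean fold error
  (GMFE = 10^mean|log10 pred/obs|), average fold error, weighted and
  percentage residuals with all eight study-level summaries, signed-rank
  zero-median tests, pooled geometric-mean-ratio confidence intervals
  classified against 0.80–1.25, and the two-fold criterion.
* **Synthetic ground truth** — a closed-form two-compartment generator
  (`generate_observed_dataset()`) that emulates sparse literature datasets
  with known parameters, kept deliberately independent of the ODE code so
  the fitting and validation stages can be tested against an external
  oracle.

## Worked example

Score the five standard doses in dogs with serum creatinine ≥ 2.4 mg/dL:

```r
library(gentadog)

pop     <- sample_population(500, stage = "scr_ge_2_4", seed = 42)
metrics <- exposure_grid(pop, doses = c(2, 4, 6, 8, 10))   # q24h x 3 days

minimal_effective_dose(
  compute_pta(metrics, efficacy_target("auc24_over_mic", 50)))
#>        stage interval_h          index mic_ug_ml dose_mg_kg
#> 1 scr_ge_2_4         24 auc24_over_mic      0.25          2
#> 2 scr_ge_2_4         24 auc24_over_mic      0.50          2
#> 3 scr_ge_2_4         24 auc24_over_mic      1.00          4
#> 4 scr_ge_2_4         24 auc24_over_mic      2.00          6
#> 5 scr_ge_2_4         24 auc24_over_mic      4.00         10
#> 6 scr_ge_2_4         24 auc24_over_mic      8.00         NA

toxicity_risk(metrics, "cmin_ge_0_5")
#>        stage dose_mg_kg interval_h   criterion risk_pct
#> 1 scr_ge_2_4          2         24 cmin_ge_0_5      4.6
#> 2 scr_ge_2_4          4         24 cmin_ge_0_5     36.4
#> 3 scr_ge_2_4          6         24 cmin_ge_0_5     65.0
#> 4 scr_ge_2_4          8         24 cmin_ge_0_5     80.0
#> 5 scr_ge_2_4         10         24 cmin_ge_0_5     88.0
```

Reduced clearance makes small doses effective (2 mg/kg already covers
MIC ≤ 0.5 µg/mL) while daily dosing quickly becomes nephrotoxic: at
4 mg/kg q24h more than a third of this population retains a trough above
0.5 µg/mL. `recommend_regimen()` combines both tables and flags the
highest-dose, longest-interval regimen that stays effective and safe, and
`run_pipeline()` executes the whole study (six stages, full dose/interval
grid, exports to CSV/JSON) from a YAML configuration.

A single dog is just as direct:

```r
m <- pbpk_model()                     # 10.5 kg healthy reference beagle
exposure_metrics(simulate_profile(m, dose_regimen(6)))
#>   auc24_day1 auc24_day3     cmax    cmin_day1  cmin_final
#> 1   35.39296   35.39296 24.98105 1.277625e-07 1.27902e-07
```

## Layout

* `R/` — physiology and populations, drug parameters and partitioning,
  ODE simulator, exposure/PTA/toxicity statistics, fitting, validation
  metrics, synthetic-data generator, pipeline.
* `src/pbpk.c` — compiled right-hand side of the mass balances.
* `inst/extdata/dog_physiology.csv` — canine organ table (per-kg volumes,
  flows, tissue composition).
* `vignettes/gentamicin-dosing-model.Rmd` — the methods vignette: model
  assumptions, calibration constants, numerical choices and limitations.
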