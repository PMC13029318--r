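---
title: "A whole-body model of gentamicin in dogs: methods, calibration and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body model of gentamicin in dogs: methods, calibration and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gentadog)
```

## The question the package answers

Gentamicin is filtered by the glomerulus and accumulates in the kidney;
its efficacy is concentration-driven (peak/MIC, AUC/MIC) while its
nephrotoxicity tracks sustained exposure (24-h AUC, trough). In a dog with
reduced glomerular filtration both sides of that balance move at once.
`gentadog` answers, by simulation: *for a dog at a given renal stage and a
pathogen at a given MIC, which dose and dosing interval are effective
without being toxic?*

## Model structure and assumptions

The dog is represented by seven compartments: arterial and venous blood,
muscle, adipose, kidney, liver, and the remaining tissues pooled into
`rest`. Each tissue is well stirred and perfusion-limited,

$$\frac{dA_i}{dt} = Q_i\left(C_{\mathrm{art}} -
  \frac{A_i}{V_i}\,\frac{BP}{Kp_i}\right),$$

so that a tissue at equilibrium holds $Kp_i$ times the plasma
concentration. This is the appropriate limit for a small, polar molecule
whose tissue uptake is not membrane-limited on the time scale of interest.
Key assumptions, each a deliberate simplification:

* **Full ionisation.** Gentamicin is a polybasic aminoglycoside; the
  parameter card carries a single acidic pKa (12.55) and the model applies
  no pH-partitioning term. Distribution is essentially extracellular,
  consistent with logP −1.6 and the calibrated Vss of ~0.20 L/kg.
* **Renal elimination only, by filtration.** CL_renal = fu × GFR × weight,
  with fu = 0.85. The filtration flux is computed at the *arterial* plasma
  concentration and debited from the kidney compartment: the glomerulus
  filters the plasma entering the kidney. Computing it at the kidney
  *outflow* concentration instead would attenuate apparent clearance by
  the factor Q_kid/(Q_kid + CL) ≈ 0.85, in conflict with the reference
  plasma clearance and with the dose/CL identity that anchors the whole
  exposure calculation. A non-renal (`cl_unspecific`) term exists but
  defaults to 0.
* **Linear kinetics.** No saturable kidney-cortex uptake. Concentrations
  are proportional to dose; the population machinery exploits this (one
  unit-dose integration per individual, scaled across the dose grid) and
  the test suite verifies linearity and superposition directly.
* **Reported concentration = arterial plasma.** Doses enter venous blood;
  reporting the *venous pool* concentration would superimpose the infusion
  inflow on the measurement, which no sampling protocol drawn away from
  the infusion site sees. Arterial sampling also keeps AUC = dose/CL
  exact. Predictions at requested times are solver outputs (the times are
  added to the integration grid), not interpolations.

## Parameters, defaults, and where they come from

Drug card (`gentamicin()`): MW 477.6 g/mol, logP −1.6, pKa 12.55,
fu 0.85, blood:plasma ratio 0.82, reference plasma clearance 0.17 L/h/kg.
A note on the clearance unit: sources sometimes quote canine gentamicin
plasma clearance in mL/min/kg with a numeral near 0.17, which cannot be
reconciled with observed exposures — a 4 mg/kg dose with an observed
AUC(0–last) of 2741.55 µmol·min/L (≈ 21.8 mg·h/L) implies
CL ≈ 4/21.8 ≈ 0.18 L/h/kg. The package therefore reads the reference as
0.17 **L/h/kg** (≈ 2.8 mL/min/kg); the acceptance suite recomputes this
consistency check from the shipped exposure fixtures.

Physiology (`dog_physiology_table()`): per-kg organ volumes and flows for
an adult dog — blood 0.085 L/kg, cardiac output 8.6 L/h/kg
(~143 mL/min/kg), muscle 0.45 L/kg at 1.1 L/h/kg, kidney 0.005 L/kg at
1.5 L/h/kg, liver (total) 2.7 L/h/kg, adipose 0.15 L/kg, rest 0.28 L/kg.
Volumes and flows scale linearly with body weight; tissue flows sum to
cardiac output to machine precision (a validated invariant). These are
implementer defaults in the physiological range for dogs, not measurements
of any single animal.

Calibration constants, chosen once and shipped as defaults:

* `kp_scale = 0.22` with `k_protein = 0.1` in the composition rule
  $Kp = \texttt{kp\_scale}(f_w + 10^{\log P} f_l + k_p f_p)$. This puts
  Vss at 0.204 L/kg — the extracellular space a hydrophilic
  aminoglycoside occupies — and, with the physiology above, an
  end-of-infusion peak of ≈ 4.2 µg/mL per mg/kg, matching observed canine
  peaks. Per-organ `kp_overrides` bypass the rule for what-if analyses.
* Healthy GFR 3.33 mL/min/kg, so that fu × GFR = 0.17 L/h/kg exactly
  reproduces the reference clearance.
* Renal-stage GFR fractions: healthy 1.0, microalbuminuria 0.80,
  UPC ≥ 2 0.50, sCr ≥ 1.2 0.40, sCr ≥ 2.4 0.20, sCr ≥ 5 0.10. The
  biomarker-to-GFR mapping is **not** a literature table; the fractions
  are package calibration constants fixed so the stages preserve their
  clinical ordering, and they are configurable wherever a stage is
  accepted.
* Between-dog variability: lognormal GFR with CV 0.15 (mean-preserving
  parameterisation) and uniform weight on 8–12 kg. No variability is
  placed on volumes or partitioning — a deliberately minimal model, since
  GFR is the covariate under study.

## Regimens and exposure metrics

Regimens are q24/36/48 h for three doses; the default administration is a
**30-minute infusion**. An instantaneous (or very short, e.g. 5-min)
injection makes the grid-maximum concentration a transient mixing spike of
order (infusion rate)/(CO × BP) that no clinical peak sample represents —
with a 5-min infusion that spike alone is ≈ 1.7 µg/mL per mg/kg on top of
the distributed peak. Slow IV infusion is also how aminoglycoside dosing
guidance says the drug should be given, and it is the administration the
Cmax/MIC index presumes. The 5-min infusions used by some historical study
designs remain available (`infusion_h = 5/60`) and are used when fitting
those studies.

From each profile the package takes: day-1 AUC24 (trapezoid over
[0, 24] h), the final-interval AUC24 (first 24 h of the last interval —
for q24h that is [48, 72] h), Cmax as the grid maximum (the grid always
contains the end-of-infusion time, where the peak of an infusion regimen
lies), and troughs immediately before the next scheduled dose (the solver
records the pre-dose limit at each dose event; the alternative clinical
practice of sampling 2–4 h before the next dose is not the default).
Efficacy uses the **day-1** AUC24, matching the definition of the
AUC24/MIC targets; toxicity uses the **final interval**, the conservative
reading of a first-and-third-day assessment under linear kinetics (the
final interval dominates day 1). Both choices are arguments, not
constants.

## Numerical choices

* `lsoda` with rtol 1e-8, atol 1e-10 mg; integration restarts at every
  dose start and infusion end, so no event is smoothed over.
* Output grid: 0.02-h steps in the first hour after each dose, 0.25-h
  elsewhere, plus all dose-event times and 24-h marks. With these steps
  the trapezoid AUC24 is within ~0.2% of the analytic value.
* The right-hand side is compiled C (8 states); one three-dose individual
  integrates in ~5 ms, which is what makes 10,000-individual populations
  practical (a 2,000-per-stage study runs in ~30 s).
* All comparisons against thresholds (PTA ≥ 90, risk ≤ 10, index ≥
  target, two-fold bounds, 0.80–1.25 GMR range) are **inclusive**, and
  PTA/risk are computed as exact counts over individuals — the test suite
  checks them against brute-force enumeration identically, not
  approximately.
* Population draws consume an isolated RNG stream (the caller's RNG state
  is saved and restored); the pipeline derives per-stage sub-seeds as
  `seed + 1000 × stage index`, so every artifact is reproducible from the
  configuration alone.

## Qualification statistics

`fold_errors()` distinguishes the magnitude measure
GMFE = 10^mean(|log10(pred/obs)|) from the signed bias measure
AFE = 10^mean(log10(pred/obs)): without the absolute value the two
formulas would coincide, so the package treats the absolute-value form as
the defining property of GMFE (hence GMFE ≥ max(AFE, 1/AFE), a tested
invariant). The signed-rank test is exact up to 25 untied non-zero
residuals and a normal approximation without continuity correction above
that (so a perfectly antisymmetric residual set reports p = 1). The pooled
GMR interval uses log-scale means/variances,
CI = GMR·exp(∓ t_{1−α/2,ν}·√(V_obs/n_obs + V_pred/n_pred)), with
Welch–Satterthwaite degrees of freedom — a documented choice, since the
pooled formula does not itself fix ν.

## The synthetic-data generator

`generate_observed_dataset()` draws sparse observed-like series (default:
dense sampling to 1 h, then 2–24 h; 3–6 subjects; multiplicative
lognormal noise, mean-one, CV 0.2) from a **closed-form two-compartment**
model rather than from the whole-body simulator, so that parameter
recovery and validation are tested against an oracle that shares no code
with the ODE machinery. Its default kinetic parameters (CL 0.17 L/h/kg,
V1 0.105, V2 0.10 L/kg, Q 1.35 L/h/kg) describe the same drug the
whole-body defaults describe — clearance and Vss agree — which is what
makes "generate, fit, recover" a meaningful round trip: noiseless data
recover the generating clearance within 1%, and 20% noise leaves the bias
under 10% across replicates.

What the generator does **not** emulate: assay quantification limits,
between-study heterogeneity in physiology, actual digitised literature
noise structure, or nonlinear kidney accumulation. Green tests therefore
demonstrate internal correctness and recoverability under the stated noise
model, not agreement with any particular clinical dataset.

## Problem sizes

The test suite runs populations of 20–2,000 virtual dogs and 20-replicate
recovery experiments; the replication script (`scripts/acceptance.R`) uses
2,000 individuals per stage, which reproduces the dose picks of a
10,000-individual study because those picks were selected for robustness
(extreme 0%/100% risk cells and minimal doses with wide PTA margins).
Counting statistics at n = 2,000 carry a standard error below one
percentage point, and the suite checks that PTA on 2,000-individual
subsamples stays within 3 points of the full population.

## Known limitations

* **No deep kidney-cortex compartment.** Real gentamicin binds and
  accumulates in renal cortex, producing a long terminal phase visible as
  measurable troughs even in healthy dogs at high doses. This model's
  terminal phase is set by muscle/adipose washout (minutes–hours), so
  trough-based risks in the *intermediate* stages are underestimated
  relative to published risk tables; the extreme cells (healthy low-dose
  0%, severe-stage 100%) are unaffected, which is why the replication
  targets use them.
* The biomarker-to-GFR fractions are calibration constants, not clinical
  measurements; for a real patient, a measured GFR should replace the
  stage label.
* IV administration only, no drug–drug interactions, no post-antibiotic
  effect or adaptive-resistance dynamics: the PK/PD indices are
  thresholds, not a pharmacodynamic kill model.
* A single composition-based partition rule with one global scale is a
  coarse description of tissue distribution; it is calibrated to Vss and
  peak behaviour, not to organ-level residue data.
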