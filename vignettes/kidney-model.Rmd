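---
title: "A mechanistic kidney model for renal digoxin disposition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic kidney model for renal digoxin disposition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephrokin)
```

## The problem

Renal excretion clearance (CL_R) of digoxin is the sum of glomerular
filtration of unbound drug, passive tubular reabsorption and active
proximal tubular secretion (OATP4C1 uptake at the basolateral membrane,
P-gp efflux at the apical membrane). In renal impairment the clinical
decline of digoxin CL_R is steeper than the decline in GFR, which a
filtration-only model cannot reproduce. nephrokin implements a
segment-resolved kidney model in which filtration, reabsorption and
secretion respond separately to changes in GFR, transporter abundance and
proximal tubule cellularity, so the candidate mechanisms can be simulated
and compared.

## Model structure and assumptions

The nephron is a chain of seven well-mixed tubular segments (PT1, PT2,
PT3, loop of Henle, distal tubule, cortical and medullary collecting
ducts) downstream of a glomerulus. Every tubular segment has a filtrate
and a cell compartment; all cells of a segment are pooled. Driving forces
are unbound concentrations: `fu_plasma` in plasma, `fu_urine = 1` in
filtrate, `fu_kidney_cell = 0.51` in cells. Passive diffusion clearance
(CL_PD, 0.01 µl/min/million cells) acts identically on the apical and
basolateral membrane of every segment. OATP4C1 uptake is linear in
unbound peritubular plasma concentration (its in vitro characterization
is linear-range only); P-gp efflux is Michaelis–Menten in unbound cell
concentration (Km 177 µM, Vmax 434 pmol/min/million cells, REF 1.51). At
therapeutic digoxin concentrations the unbound cell concentration is
orders of magnitude below Km, so the whole system is effectively linear
and CL_R is dose-independent (verified to 0.5% in the tests).

**Blood side.** Glomerular filtration is driven by the arterial plasma
concentration, so with all transport and permeability off CL_R equals
`fu_plasma × GFR` to machine precision — a structural identity used as a
test oracle. Basolateral exchange and OATP4C1 uptake draw on a single
well-stirred peritubular pool with plasma-equivalent flow
`RBF·B:P − fu_plasma·GFR` (the drug flow remaining after filtration).
This makes the flow limitation emergent rather than imposed: as the
uptake capacity grows, the pool depletes and CL_R saturates smoothly
below `RBF·B:P` (1100 ml/min at default physiology). We chose pool
depletion over a hard extraction cap because a capped model has no
intermediate saturation regime, while the observed behaviour at very
high intrinsic clearance (CL_R ≈ 800 ml/min at CL_int,T = 270
µl/min/10⁶ cells) sits well below the cap. Per-segment peritubular flows
are not identifiable from any observable this model targets, so a single
pool is the simplest adequate structure.

**Cellularity.** Total proximal tubule cells are
`PTCPGK × kidney weight` (60 million cells/g × 380 g by default), split
equally over PT1–PT3. Distal segment cellularity is tied to the proximal
total with fixed ratios (0.3, 0.2, 0.1, 0.1 for LoH, DT, CCD, MCD), so
the PTCPGK parameter rescales every tubular segment — which is why
reducing PTCPGK also reduces passive reabsorption, while reducing
transporter abundance per cell does not. This asymmetry is the model's
central mechanistic contrast.

**Water handling.** Filtrate flow at segment exits is a fixed fraction of
GFR through the distal tubule (0.71, 0.49, 0.34, 0.25, 0.11 of GFR —
glomerulotubular balance), then floored at an absolute urine flow of
1 ml/min. The floor encodes the loss of urinary concentrating capacity in
chronic kidney disease: daily urine volume in moderate/severe impairment
is roughly preserved while GFR falls. A consequence worth knowing: at
very low GFR the last segments carry equal flows (nonincreasing, not
strictly decreasing), and the luminal concentration factor falls, which
keeps the fraction reabsorbed from exploding as filtrate slows.

**Serum creatinine and GFR.** The model maps serum creatinine to absolute
GFR with the classic Cockcroft–Gault equation (creatinine in µmol/l,
multiplier 88.4/72; female × 0.85), capped at 180 ml/min — the
conventional hyperfiltration threshold. The cap matters only at low
creatinine (< ~66 µmol/l for the reference demographics): uncapped, the
1/SCr form would assign the representative a GFR above 220 ml/min at
SCr 54 µmol/l, which is physiologically implausible and would make the
estimated OATP4C1 CL_int,T vary almost 6-fold across a 54–108 µmol/l
creatinine band instead of the roughly 2-fold spread the estimation
analysis is designed to exhibit. The scenario grid (GFR 136.4 down to 15
ml/min/1.73 m²) sits entirely below the cap, so scenario arithmetic is
pure Cockcroft–Gault.

## Calibration (performed once, frozen)

Three quantities are not printed anywhere and were calibrated once
against the model's own anchor values, then frozen in `R/constants.R`:

1. `fu_plasma = 98.8/156 ≈ 0.633`, so that filtration-only CL_R of the
   healthy representative (SCr 76.5 µmol/l ⇒ GFR 156 ml/min) is exactly
   98.8 ml/min. Literature plasma binding of digoxin is fu ≈ 0.71 with a
   somewhat lower effective filtration rate; only the product is
   observable here, and we let fu absorb the whole calibration because
   GFR is pinned by the creatinine mapping.
2. A distal surface-area factor `κ = 8.61` multiplying CL_PD in LoH, DT,
   CCD and MCD, calibrated so the fraction reabsorbed is 0.12 at CL_PD =
   0.01 µl/min/10⁶ cells. With strictly per-cell scaling and realistic
   cell counts, the stated CL_PD yields F_reab < 0.02; per-cell
   permeability times cell number is simply not a good surface model for
   the water-permeable distal epithelium, and the per-segment surface
   differences are acknowledged as unmodelled in the source
   parameterization. The proximal factor stays 1 so the printed CL_PD
   retains its meaning there.
3. Reference kidney weight 380 g (both kidneys), calibrated so CL_R at
   the estimated CL_int,T of 4.14 µl/min/10⁶ cells equals 133.4 ml/min
   for the representative at SCr 80 µmol/l. This is the secretion scale;
   380 g is heavier than the textbook 300 g because part of the secreted
   flux is reabsorbed distally and must be overcome.

No constant is adjusted after these three solves; every reported number
downstream (population means, sweep ratios, estimation results) is an
emergent consequence.

## Virtual populations

Population conditions are declared in `population_spec()` and fixed:

| population | primitive | demographics | kidney wt | fu factor | hct |
|---|---|---|---|---|---|
| healthy | SCr ~ lognormal, median M 66 / F 56 µmol/l, CV 15% | 20–50 y, 50/50 sex | ×1.00 | 1.00 | 0.45 |
| geriatric | SCr median M 74 / F 61 | 65–85 y | ×0.90 | 1.00 | 0.42 |
| moderate RI | GFR ~ U[30, 60) ml/min/1.73 m² | 40–70 y | ×0.80 | 1.05 | 0.40 |
| severe RI | GFR ~ U[15, 30) | 40–70 y | ×0.55 | 1.10 | 0.35 |

Healthy and geriatric sample serum creatinine (GFR derived); impairment
populations sample the GFR band (creatinine derived). The serum
creatinine medians were chosen once so the healthy population mean
normalized GFR lands near the representative's (≈134 ml/min/1.73 m²) and
the geriatric mean is ≈56% of healthy; kidney-weight factors for the
impairment groups were calibrated to the published population mean
clearances and then frozen. Renal blood flow scales with kidney weight.
Between-subject variability is lognormal with 30% CV on OATP4C1, P-gp
and CL_PD multipliers (mean-1 parameterization). Mechanism sweeps pair
the impaired and control arms on a shared seed to cancel demographic
Monte-Carlo noise from the ratios.

## Estimation

The sensitivity-analysis estimator simulates the CL_R(CL_int,T) curve at
fixed serum creatinine on a 21-point grid over 0–20 µl/min/10⁶ cells,
interpolates with a monotone (Hyman-filtered) cubic spline and returns
the crossing with the observed clearance by root bisection; an observed
value outside the simulated range is a hard "no crossing" error. The
profile fitter minimizes the sum of squared residuals on log
concentrations (multiplicative error) over CL_int,T alone with golden
search on [0, 20]; P-gp parameters are never estimated — they are
practically nonidentifiable from plasma and low-resolution urine data —
and the zero boundary is an admissible, flagged estimate. Per-study
estimates are pooled by subject-number weighting. Note that the direct
subject-weighted mean of the nine published per-study fits is 2.11
µl/min/10⁶ cells, and the tests freeze that arithmetic; the smaller
published pooled value is used in this package only as a
forward-simulation input.

## Synthetic data

`gen_clinical_dataset()` emulates a mean-profile clinical study: the
coupled model is simulated at known ("true") parameters, plasma samples
and interval urine amounts are read off the solution, and multiplicative
lognormal error is applied per observation. It reproduces sampling
schedules, infusion durations and residual spread of mean profiles; it
does **not** emulate between-subject variability within a study, drug
assay limits of quantification, or dropout — parameter-recovery results
therefore show estimator correctness, not expected precision in a real
sparse-data meta-analysis. For recovery studies at a nominal
between-subject CV of 15% with n subjects, the residual on the mean
profile is taken as 0.15/√n. `gen_meta_analysis_fixture()` builds
study-level clearance tables with known grand mean for testing the
pooling arithmetic. All generators restore the global RNG state and are
byte-reproducible under a fixed seed.

## Numerics

Internally amounts are pmol, volumes ml, time minutes, concentrations
pmol/ml; conversion happens only at interfaces (mg doses, ng/ml output,
µg·min/ml AUC). The steady-state solver assembles the 15-unknown linear
system (peritubular pool, 7 cell, 7 filtrate concentrations) and
iterates the P-gp conductance `Vmax·N/(Km + Cu)` to a 1e-12 fixed point —
one iteration suffices in the linear regime. Degenerate segments (no
exchange paths) get an identity row instead of a singular one. The
dynamic solver is `deSolve::lsoda` with rtol 1e-8 / atol 1e-10, output
refined around the infusion end for C_max,PT-1; the peritubular pool is
quasi-steady and algebraic, so mass is conserved by construction
(verified to ~1e-9 relative in tests). Dynamic CL_R is cumulative urine
divided by plasma AUC over the same window, which is
window-independent for a time-invariant linear system; AUC to infinity
adds a log-linear tail from the last six points. Filtrate compartment
volumes use a ~1-minute transit time and cells 5 pl each; these shape
early transients only.

Problem sizes: tests run populations of 12–50 subjects and dynamic
horizons of 24 h; the acceptance script uses the full 100-subject
populations and 48-h horizons. One dynamic simulation takes ~0.1 s, one
steady-state solve well under a millisecond.

## Known limitations

* The creatinine→GFR mapping is Cockcroft–Gault with a ceiling; no
  MDRD/CKD-EPI, no pediatrics, no end-stage renal disease.
* Net secretion interacts with reabsorption: below GFR ≈ 100 ml/min part
  of the secreted drug is reabsorbed distally, so "secretion preserved
  under pure-GFR reduction" holds exactly for the uptake flux but only
  approximately for net secretion reaching urine.
* Single peritubular pool: no axial blood-side gradients, no
  segment-specific transporter expression gradients.
* P-gp parameters are carried, not validated; the model is not suitable
  for P-gp-mediated interaction predictions, only for showing CL_R
  insensitivity and cell-concentration sensitivity to P-gp abundance.
* Urine-flow dependence of CL_R and pH effects are not modelled; the
  two-compartment systemic constants shape profiles only (AUC and CL_R
  are insensitive to them in the linear regime).
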