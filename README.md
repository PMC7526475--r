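# afablate

Desk-scale *in silico* trials of catheter-ablation strategies for atrial
fibrillation (AF) on synthetic left-atrial (LA) surface models.

## The problem

Catheter ablation for AF starts from pulmonary vein isolation (PVI) and may
add lesions that target the anatomical substrate (posterior-wall box
isolation), the structural substrate (fibrotic tissue seen as high
late-gadolinium-enhancement, LGE, intensity), or the electrical substrate
(re-entrant driver sites mapped as phase-singularity hotspots). Which
addition helps which patient is an open question. `afablate` builds a cohort
of virtual patients, simulates AF on each of them, applies six automated
lesion sets, classifies the acute outcome of each, and trains a machine-
learning model to predict acute ablation response — so the whole trial
is reproducible from a couple of seeds on a laptop.

It is aimed at cardiac-electrophysiology modellers and methods researchers
who want a self-contained, fully synthetic test bed for ablation-planning
and driver-mapping pipelines.

## What is inside

- **Synthetic cohort** — seeded virtual patients: an ellipsoid-like LA shell
  clipped at the mitral valve (MV) and four pulmonary veins (PVs), region
  labels, a two-coordinate surface chart (septal–lateral and MV-to-roof,
  analogous to universal atrial coordinates), a smooth fiber field, and an
  LGE intensity map with blood-pool reference statistics, calibrated so
  cohort LA areas and fibrotic burdens match a published AF cohort
  (paroxysmal ≈ 102 cm², persistent ≈ 120 cm² LA area; ≈ 23 / 26 cm²
  fibrosis).
- **Fibrosis model** — normalized LGE intensity maps to conduction-velocity
  bands (100 / 80 / 60 / 40 % of baseline at the 0.56 / 0.60 / 0.64
  thresholds) with conductivity scales calibrated on a tissue strip, and
  blood-pool z-scores > 3 trigger ionic remodeling
  (gK1 × 0.5, gNa × 0.6, gCaL × 0.5) on top of LA, PV, appendage and
  AF-remodeling conductance changes.
- **Monodomain solver** — anisotropic P1 finite-element surface operator
  (σ_l = 0.4, σ_t = 0.1 S/m baseline, tensor σ_l f fᵀ + σ_t (I − f fᵀ))
  with a two-variable phenomenological (Mitchell–Schaeffer) ionic surrogate,
  stepped explicitly in compiled code; AF is initiated from four Archimedean
  spirals (two per wall, alternating chirality).
- **Phase mapping** — Hilbert-transform phase, per-element topological
  charge for phase-singularity (PS) detection, geodesic-Gaussian PS density
  maps, hotspots at mean + 1 SD with connected-component segmentation.
- **Ablation planner** — six strategies: PVI, posterior box (roof line at
  chart coordinate 0.5, inferior line at 0.15), largest / all fibrotic
  regions, largest / all PS hotspots, each joined to the closest boundary
  or lesion; lesions become zero-conductivity, inexcitable tissue.
- **Outcomes** — termination / atrial tachycardia (AT) / AF by a 4.7 Hz
  dominant-frequency rule (Welch spectra), the five lesion metrics
  (remaining LA / fibrosis / hotspot area, conducting roof width, smallest
  MV channel), and per-patient optimal-strategy selection.
- **Responder classifier** — a random forest over imaging, electrical and
  lesion features with an anatomy-grouped 70:30 split, grouped 5-fold
  cross-validation on balanced accuracy over the frozen hyperparameter grid,
  logistic-regression and SVC baselines, and permutation-Shapley feature
  attributions with exact local accuracy.

## Worked example

```r
library(afablate)

patient <- generate_cohort(1, 0, seed = 7)[[1]]
print(patient)
res <- evaluate_patient(patient)   # ~15 s: 2 s AF + 6 x 1.5 s post-ablation
```

```
Virtual patient paro_01 (paroxysmal AF), seed 7007941
Synthetic atrial surface
  2278 vertices, 4427 triangles, 5 boundary loops
  total area 94.1 cm^2; LA body area 85.8 cm^2
pre-ablation mean DF: 4.84 Hz; hotspot area: 16.1 cm^2
pvi              ablated  18.0 cm^2  remaining  60.6 cm^2  outcome AT
box              ablated  22.7 cm^2  remaining  50.9 cm^2  outcome AT
single_fibrosis  ablated  30.7 cm^2  remaining  51.3 cm^2  outcome AT
all_fibrosis     ablated  38.5 cm^2  remaining  44.0 cm^2  outcome AT
single_hotspot   ablated  25.9 cm^2  remaining  52.8 cm^2  outcome AT
all_hotspots     ablated  34.7 cm^2  remaining  48.1 cm^2  outcome AT
optimal strategy: pvi
```

This patient's AF (mean dominant frequency 4.84 Hz) converts to AT under
every strategy, so the optimal choice is the one with the smallest ablation
burden — PVI alone. A full trial (cohort → outcomes → feature table →
classifiers) is one call:

```r
tr <- run_trial(trial_config(n_paroxysmal = 4, n_persistent = 6, seed = 1))
print(tr)            # outcome tally per strategy, optimal-strategy
                     # distribution, classifier reports
```

A thin command-line wrapper is installed at
`inst/scripts/run_trial.R` (`Rscript run_trial.R --seed 1 --out trial_out`).

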