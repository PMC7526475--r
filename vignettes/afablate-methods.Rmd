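---
title: "Methods: virtual AF ablation trials on synthetic atria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual AF ablation trials on synthetic atria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`afablate`, and states explicitly what the synthetic test bed does and does
not show about real atria.

## Overview of the pipeline

For each virtual patient the trial runs:

1. geometry + LGE map generation (`generate_cohort`),
2. tissue translation: conduction-velocity (CV) bands, blood-pool z-scores,
   ionic multipliers (`build_tissue`),
3. pre-ablation AF from a four-spiral initial state (`init_spiral_field`,
   `run_simulation`),
4. phase-singularity (PS) mapping and hotspot segmentation
   (`compute_phase`, `track_ps`, `ps_density`, `find_hotspots`),
5. six lesion sets (`plan_all_strategies`), each applied electrically and
   re-simulated from the pre-ablation end state,
6. outcome classification and lesion metrics (`classify_outcome`,
   `compute_lesion_metrics`), optimal-strategy selection,
7. a responder random forest with grouped cross-validation and Shapley
   attributions (`fit_responder_model`, `feature_attribution`).

## The synthetic cohort

The left atrium is modelled as an ellipsoid-like shell (icosphere
subdivision scaled by jittered radii) with five geodesic disks removed: the
mitral valve (MV) and four pulmonary veins (PVs), placed as two ipsilateral
pairs on the posterior aspect with the MV antipodal to the roof. This is
the minimal anatomy that carries the topology the ablation strategies need
(five boundary rims, a posterior wall bounded by the PV pairs, a roof
between the superior veins). The appendage is a labelled region, not a
pouch.

The surface chart mimics the role of universal atrial coordinates:
coordinate 1 is the azimuth around the MV axis (anterior wall < 0.5 ≤
posterior), coordinate 2 runs from the MV rim (0) to the roof pole (1) so
the roof line sits at 0.5 and the inferior line at 0.15. It is defined
analytically from the generating parameterization; the published
coordinate-solving algorithm itself is out of scope.

LGE intensity is baseline 100 plus geodesic Gaussian blobs plus white
noise, with synthetic blood-pool statistics (mean 80, SD 10) stored as
metadata, so "3 SD above the blood pool" has the same meaning as in imaged
maps. Blob centers are drawn with a proximity weight toward the PV antra
(correlation scale 15 mm plus a uniform floor), reflecting the
posterior/antral predominance of clinical atrial fibrosis. Generator
parameters were calibrated once against the published cohort statistics
(mean LA body area 102.1 / 120.1 cm² and fibrotic area 23.2 / 26.2 cm² for
paroxysmal / persistent presets) and then frozen; per-patient variability
(radius ~9.5 % lognormal, hole jitter 0.04 rad) is our choice, since the
anatomical variability of the source cohort is not quantified.

What the generator does **not** emulate: PV sleeve tubes (so PV surface
area is smaller than the published 28–30 cm²), wall thickness and the
endo–epicardial bilayer, appendage geometry, MRI noise structure and
segmentation error. Consequently, passing tests show the *pipeline* behaves
correctly on anatomies with the right areas, topology and fibrosis
statistics — not that its quantitative outputs transfer to patient meshes.

## Tissue model

* Baseline conductivities: longitudinal 0.4 S/m, transverse 0.1 S/m.
* CV bands on per-patient min–max normalized LGE: 100 % for [0, 0.56),
  80 % for [0.56, 0.60), 60 % for [0.60, 0.64), 40 % for ≥ 0.64. The
  half-open, left-closed convention resolves the overlapping printed range
  endpoints deterministically. Elements take the worst band of their
  vertices (conservative slowing). Normalization is per patient; a
  cohort-wide normalization would couple patients through a single
  maximum.
* Band conductivity scales were found by bisection on a 40 × 10 mm strip
  (pacing one end, CV between probes at 25 % and 75 % length, 2 % relative
  tolerance) and frozen: 1.0, 0.640, 0.376, 0.175. The continuum limit
  (CV ∝ √σ) predicts 1.0, 0.64, 0.36, 0.16; the small excess at low scales
  is the discrete wavefront on a 0.5 mm strip mesh.
* Ionic multipliers compose multiplicatively across the four layers
  (LA baseline, region, AF remodeling, fibrotic). The multiplicative
  reading of "50 % of the regional value" is a design decision; it makes
  the result independent of application order.

## Monodomain surrogate

The solver integrates the monodomain equation on the surface with a P1
finite-element stiffness matrix (element tensor σ_l f fᵀ + σ_t (I − f fᵀ),
lumped mass, natural no-flux boundaries) and Mitchell–Schaeffer two-current
kinetics on a normalized voltage (mapped to mV as −80 + 100 V). A
two-variable phenomenological surrogate was chosen over a three-variable
one because it has fewer couplings to tune once and supports stable
re-entry; a full human atrial ionic model would not be tractable at the
cohort scale this package targets and is not implemented.

Frozen kinetics: τ_in = 0.3 ms, τ_out = 6 ms, τ_open = 110 ms,
τ_close = 150 ms, V_gate = 0.13. Named-channel multipliers map onto the
surrogate by a fixed table: τ_in divides by the gNa multiplier
(excitability / CV), and τ_close scales by
gCaL^0.45 · gK1^(−0.25) · gto^(−0.1) · gKur^(−0.1) · gKr^(−0.1) ·
gKs^(−0.05) (action-potential duration shortens when inward calcium drops
or repolarizing currents grow). The exponents were tuned once so that
(a) AF-remodeled tissue sustains re-entry for the analysis window on the
default cohort and (b) dominant frequencies land near the ~4.9 Hz regime,
then frozen. The conductivity-to-diffusivity constant is 0.75
(mm²/ms)/(S/m), i.e. 0.4 S/m ↦ 0.3 mm²/ms, a standard atrial value; with
it the baseline strip CV is ≈ 0.57 mm/ms.

Numerics: single forward-Euler step for reaction and diffusion at
dt = 0.1 ms, frames every 5 ms. The explicit diffusion step is far below
the stability bound at desk resolutions (≈ 2 mm edges); the bound is
checked against the Gershgorin estimate at run time and refining dt by two
moves strip activation times by < 1 ms (tested). Ablated elements get zero
conductivity; vertices whose entire one-ring is ablated are clamped to
rest, which is why lesions are built at least two element rings wide —
otherwise FEM vertex coupling lets excitation tunnel through a
one-element-wide line.

AF is initiated as an activation-time field of four Archimedean spirals
(pitch λ = 0.12 chart units, 2–3 turns per wall) with alternating
topological charge, two per wall, at frozen chart positions
(coordinate 1 = 0.13, 0.37, 0.63, 0.87; coordinate 2 = 0.45) — the
supplementary construction of the source protocol is not public, so these
defaults are the package's own. The phase field is built in the chart
*disk* ((1 − c₂)·e^{2πi c₁}), which is continuous across the chart seam, so
the initial phase map contains exactly the four seeded singularities. Each
vertex's state is the reference-cycle state (one paced cable beat) at its
activation phase; the default cycle length is 330 ms.

## Phase mapping

Phase is the angle of the analytic signal (FFT-based Hilbert transform) of
the mean-subtracted voltage; vertices with trace SD below 1 mV are invalid
and excluded from the density statistics. Charge is the wrapped phase
circulation around each triangle; the state-space (V, dV/dt) phase variant
was not used because the analytic-signal construction is standard and
directly testable against a winding-number oracle. PS density is the
geodesic-Gaussian-smoothed event count (σ = 5 mm default), normalized so
the surface integral times the window equals the event count; hotspots are
connected components above mean + 1 SD. Frame-to-frame PS linking is not
needed for density and is not part of the pipeline.

## Ablation planning

* PVI: elements crossed by the geodesic contour at 5 mm from the PV/body
  junction (union over veins, so close ipsilateral veins merge into one
  wide-area band), dilated one ring; validated by checking every PV rim is
  disconnected from the MV rim. 5 mm and the 3 mm lesion width are package
  defaults; the source protocol quantifies neither.
* Box: PVI plus roof (coordinate 2 = 0.5) and inferior (0.15) lines across
  the corridor between the superior PV azimuths, validated by checking a
  posterior and an anterior probe element land in different components.
* Region isolation: the selected fibrotic/hotspot regions are ablated in
  full (interior ablation — "selected for ablation" is read literally) in
  descending area order, each joined by a widened geodesic shortest path to
  the closest of the mesh boundaries or the lesion components built so
  far; exact ties prefer boundaries, then lower component index, for
  determinism.

## Outcomes and metrics

Termination is the earliest time after which no vertex crosses −40 mV for
300 ms. Otherwise the mean dominant frequency over non-quiescent LA-body
vertices decides: ≤ 4.7 Hz is AT (the boundary goes to AT, the conservative
reading of the strict printed inequalities), > 4.7 Hz is AF. Spectra are
Welch periodograms with 2 s Hann windows, 50 % overlap, zero-padded to
0.05 Hz resolution; shorter post-ablation records use a single full-length
window — a documented desk-scale deviation from the 15 s analysis window.
Averaging over the body only (PVs excluded) is a package decision.

Roof width is the conducting length of the coordinate-2 = 0.5 isocontour
inside the inter-superior-PV corridor, restricted to the largest
post-ablation region; on this closed chart the full isocontour is a closed
circle, so the corridor restriction keeps the metric a "roof" measurement.
The smallest channel is the minimum Euclidean MV-rim-to-lesion distance
over lesion components larger than 80 % of the second-largest component.
Optimal strategy = best outcome category (termination > AT > AF), ties by
smallest ablated area; the largest-remaining-region variant is reported
alongside.

At the default 1.5 s post-ablation window the termination category is rare
(activity must stop 300 ms before the record ends), so outcomes are
effectively AT vs AF; responder status (AT or termination) is unaffected.

## Responder classifier

300-row design (50 anatomies × 6 strategies at full scale): strategy
one-hot plus 3 imaging, 2 electrical and 5 lesion features; label 1 = AF
(non-responder). The 70:30 split is grouped by anatomy, and — stricter than
the source protocol states — the 5-fold cross-validation folds are grouped
by anatomy too, to prevent leakage between folds. The grid is frozen
(trees 10–100, depth 4/8/16, min leaf 5/10/20), selection by balanced
accuracy, final fit class-balance weighted; precision and recall are
support-weighted two-class averages (the averaging convention is not
stated in the source). Baselines: ridge logistic regression with the
regularization path chosen by the same grouped CV, and an RBF SVC over a
small cost/γ grid.

Attributions are interventional Shapley values estimated by sampling
feature-entry permutations against a background sample, with the six
strategy one-hot columns acting as one player. The telescoping sum makes
the attributions add up to prediction minus mean background prediction
*exactly* at any number of permutations, so local accuracy is a structural
property; 10–20 permutations and ~25 background rows are enough for stable
rankings at this problem size.

## Problem sizes and determinism

Default desk scale, chosen as the package's own operating point: mesh edge
≈ 2 mm (≈ 2,300 vertices), 10-patient cohorts (4 paroxysmal + 6
persistent), 2 s pre-ablation and 1.5 s post-ablation windows, dt = 0.1 ms.
Everything is deterministic given the seeds: per-patient seeds derive from
the cohort seed by a fixed integer recurrence, simulations contain no
randomness, and the classifier seeds the split, the folds and the forests.

## Known limitations

Single-layer monodomain surface (no bilayer, no wall thickness); no
triggered-beat protocols, so the trial measures AF *maintenance*, not
inducibility; a phenomenological ionic surrogate, so restitution and drug
effects are caricatures; synthetic hotspot locations need not colocate
with the PV antra the way clinically mapped drivers often do — on this
cohort, hotspot-targeted lesion sets therefore remove more of the main
conducting region than antrum-anchored drivers would; and acute outcome at
seconds is not long-term outcome.
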