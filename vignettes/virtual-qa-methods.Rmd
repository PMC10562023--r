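---
title: "Virtual patient-specific QA for VMAT: methods and design notes"
author: "vmatqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual patient-specific QA for VMAT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

## The problem

Before a volumetric-modulated arc therapy (VMAT) plan is delivered, clinics
verify that the dose the machine actually delivers matches the dose the
treatment planning system computed. The conventional check measures the
delivered dose on a phantom with a detector array and compares it to the
calculation with the gamma index; the fraction of points passing a
dose/distance criterion — the gamma passing rate (GPR) — is the acceptance
statistic. Measurement-based QA is accurate but slow and machine-hungry.
"Virtual" QA replaces the measurement with a prediction: a model that, given
only the plan and its calculated dose, predicts the GPRs a measurement would
have produced.

`vmatqa` implements such a pipeline end to end for single-arc VMAT plans
with a 60-pair MLC:

1. **Plan ingestion** (`readRtplan`, `readRtdose`): DICOM RT-Plan control
   point sequences and RT-Dose grids.
2. **MLC leaf-position map** (`buildLeafMatrix`, `findAlwaysClosedPairs`,
   `buildMlpm`): the plan's whole MLC trajectory as one image.
3. **Dose-plane inputs** (`extractIsocenterPlanes`, `extractSurfaceDose`):
   fixed-size sagittal/coronal/axial planes through the isocenter, and an
   unrolled cylindrical surface map.
4. **Gamma engine** (`gammaMap`, `gpr`, `gprVector`): global gamma at the
   nine criteria {1,2,3}% × {1,2,3} mm with a 10% low-dose threshold.
5. **Prediction network** (`buildNetwork`, `trainModel`, `predictGpr`):
   a light multi-branch CNN regressing all nine GPRs at once.
6. **Synthetic cohort** (`generatePlan`, `simulateDose`, `generateDataset`):
   a simulator that stands in for a clinical dataset so the whole pipeline
   is testable.

## The MLC leaf-position map

Scalar complexity metrics (MCS and relatives) compress the MLC trajectory
into one number and provably discard information. The leaf-position map
(MLPM) instead keeps everything: rows are the 120 leaves (bank A leaf 1
through bank B leaf 60), columns are control points, and each cell is the
leaf's displacement from its closed-state coordinate, so a closed leaf reads
exactly 0 and openness/motion appear as image structure.

Design choices worth calling out:

* **Absolute displacement.** The map stores `|position − junction|`. A
  signed variant would distinguish over-travel from under-travel, but the
  closed state would then not be a unique zero; we keep the magnitude and
  note the alternative.
* **Closed-state reference.** The junction of a pair is estimated as the
  tip midpoint averaged over the control points where the pair is closed
  (gap ≤ 0.5 mm), falling back to the all-control-point midpoint for pairs
  that never close. For symmetric apertures both estimates coincide.
* **Closure tolerance 0.5 mm.** Of the order of the dosimetric leaf gap;
  leaf pairs parked "closed" in real plans jitter by fractions of a
  millimetre.
* **Always-closed pairs.** Rows of pairs that never open anywhere in the
  cohort carry no information and are removed — by default 5 pairs, taking
  120 rows to 110. The exclusion set is a *dataset-level* quantity; when
  training on real data it should be computed on the training split and
  frozen (the synthetic generator pins the closed set by construction, so
  the point is moot there).
* **Fixed width 178.** A full Varian arc has 178 control points. Shorter
  arcs are right-padded with zeros (padding a closed state fabricates no
  motion); longer ones are rejected rather than truncated.
* **Normalization.** Network inputs are divided by the dataset-wide maximum
  displacement (and dose planes by the dataset-wide maximum dose), mapping
  to [0, 1]; the constants are stored with the dataset.

## Dose-plane inputs

The three anatomical planes through the isocenter are cut at native grid
spacing and center-cropped / zero-padded to fixed shapes (default
68×146, 64×200, 143×242) with the isocenter on the centre pixel. Cropping
rather than rescaling preserves dose-gradient magnitudes, which is what the
gamma index responds to. The cylindrical surface map (default radius 105 mm,
220 axial × 680 azimuth bins) emulates a diode-array-style view; its exact
geometry is a package choice — nothing in the prediction pipeline depends on
it beyond the printed input shape.

## Gamma engine

Global gamma: dose differences are normalized by the maximum of the
reference distribution; reference points below 10% of that maximum are
excluded. For each reference point the engine minimizes
$\sqrt{\Delta r^2/\delta^2 + \Delta D^2/(\tau D_{max})^2}$ over evaluated
positions within `3·dta` of the point, sampling the evaluated image by
bilinear interpolation on a `0.1·dta` sub-grid, visiting candidates in order
of increasing distance so the search stops once the distance term alone
exceeds the running minimum (an exact, not approximate, speedup). A GPR is
the percentage of in-domain points with gamma ≤ 1.

Numerical parameters (`searchMult = 3`, `stepFrac = 0.1`) are package
choices — commercial QA software does not publish its internals, so exact
numerical agreement with any vendor is out of reach; the test suite instead
proves equivalence with an exhaustive brute-force search when the
interpolation lattice coincides with the sample grid, and with an
independent plain-R implementation of the same definition elsewhere.

A subtlety: with the step tied to `dta`, the candidate sets of different
criteria are not nested, so GPR monotonicity in the DTA tolerance is not a
theorem of the discretization — it is asserted empirically (and holds) in
the tests.

## Network

Each input image gets its own branch: Conv 3×3 (same-padded) → MaxPool
3×3/3 → Conv 3×3 (valid) → MaxPool → Conv 3×3 (valid) → MaxPool → flatten →
affine to a 20-unit embedding; all convolutions have 16 channels. Three
convolution stages keep the parameter count small relative to the cohort
size — overfitting, not capacity, is the binding constraint at fewer than a
hundred training plans. Branch embeddings are fused by elementwise addition
(the printed fusion width, 20, equals the embedding width, which rules out
fusing after the scalar heads), then ReLU → batch norm → dropout 0.3 →
20×20 affine → nine parallel 20→1 heads, one per criterion. The multi-task
head shares almost all parameters across criteria, which regularizes the
stringent criteria where labels are most spread.

Model variants differ only in branches: `model1` = three dose planes +
MLPM, `model2` = dose planes only, `model3` = surface map only.

* Batch norm uses the standard 2 learnable parameters per feature
  (40 in total) plus running statistics. Published parameter tables from
  some frameworks count 4 accounting entries per feature; only weights and
  biases are counted here.
* Initialization is Glorot-uniform, biases zero, seed-controlled.
  Everything downstream (shuffling, dropout masks) draws from R's RNG, so a
  `(dataset, seed)` pair reproduces training bit for bit on one machine.
* Labels are trained on a [0, 1] scale (GPR/100) and reported in percent.
* Loss is mean squared error averaged uniformly over the nine outputs.
* Training follows the fixed protocol: 200 epochs, batch size 4, Adam at
  learning rate 0.001; the adopted weights are those of the epoch with the
  smallest validation loss (ties toward the earlier epoch). Data are split
  3:1 train/test by seeded shuffle (4-fold cross-validation) with 20% of
  the training portion held out for validation; no stratification.
* Evaluation: per criterion, MAE, Pearson r and the fraction of predictions
  within ±3 percentage points, computed per fold on the pooled test
  predictions and averaged (mean ± SD) across folds. Zero-variance folds
  flag r as undefined rather than propagating NaN.

## The synthetic cohort

No public dataset of VMAT plans with measured GPR labels exists, so the
package ships a simulator whose only job is to produce data with the
*statistical structure* the method assumes: plans of varying modulation,
planned and "delivered" doses whose differences grow with delivery error,
and nine-criterion labels that are mostly high with a long lower tail.

* **Plans.** Sixty leaf pairs; five pinned always-closed (110 map rows); an
  elliptically tapered target aperture (central pairs widest, as for a
  central target) with per-control-point random-walk jitter on gap and
  centre, clipped to ≤ 3 mm leaf travel per control point; per-plan target
  mean gap drawn from 10–34 mm as the complexity axis; a full 358° arc and
  a random non-uniform cumulative meterset.
* **Dose.** 2D arc accumulation of binary aperture fluence: a voxel
  receives a control-point interval's meterset weight when its beam-axis
  coordinate falls inside the aperture of the leaf pair covering its z
  position (2.5 mm leaf bands), followed by a 1.5 mm Gaussian penumbra
  blur; default grid 56×56×20 at 1.5 mm. This is deliberately a toy — no
  divergence, attenuation or scatter modelling — because the pipeline needs
  dose *structure*, not transport fidelity.
* **Delivery error.** Four knobs per plan: a systematic aperture-opening
  leaf offset whose local magnitude scales with leaf speed (dynamic-lag
  behaviour: a stationary leaf sees half the nominal offset, a leaf at the
  travel limit twice it), per-leaf position noise held fixed along the arc
  (calibration-type error that does not average out over control points),
  a global output scaling, and extra spatial blur. The zero model
  reproduces the planned dose exactly, by construction.
* **Labels.** Global gamma of planned (reference) vs delivered (evaluated)
  on the central axial plane at all nine criteria — a planar stand-in for
  an array measurement.
* **Small-field output deficit.** On top of the sampled error, the
  delivered output of a plan is reduced by
  `amplitude·exp(−meanGap/scale)` (defaults 5% amplitude, 15 mm scale):
  heavily modulated apertures lose a few percent of output, the small-field
  dosimetry behaviour delivery shows but simple planning calculations
  underestimate. This term is deterministic given the plan — it is part of
  the plan-predictable structure the model is supposed to learn — and is
  suppressed for a plan whose sampled error is exactly zero, preserving the
  zero-error identity.
* **Error magnitudes across a cohort** are drawn from a mixture — mostly
  small (leaf noise ≈ 0.6 mm, offsets ≈ ±0.3 mm), occasionally large — so
  the label distribution shows the long lower tail clinical QA data have:
  at 3%/3 mm labels sit almost entirely in 90–100%, at 1%/1 mm they spread
  broadly over roughly 70–100% with a minority of worse outliers.

What passing tests on this cohort do and do not show: they demonstrate that
the pipeline can extract genuinely predictive structure from the MLPM and
dose planes when such structure exists, and that every contract
(shapes, invariants, reproducibility) holds. They say nothing about
clinical accuracy — clinical-scale accuracy figures require a measured
cohort of plans with array-measured passing rates, which this package
deliberately does not claim to replace.

## Problem sizes used in the automated experiments

The shipped tests and the acceptance script run the full pipeline at a
reduced scale chosen so the end-to-end experiment remains a desk-scale
computation: 96 plans of 60 control points, 52×52 dose planes and a 110×60
MLPM (the smallest images the three conv/pool stages accept are 51×51),
the default 1.5 mm toy dose grid, 200 training epochs, and a single
cross-validation fold per seed for the model comparison. Architecture
conformance is always checked at the full standard input sizes; only the
learning experiments are scaled down.

## Known limitations

* The dose engine is 2D-accumulation-with-blur; absolute dose levels are
  arbitrary (meterset-weighted fluence), so only relative comparisons and
  gamma statistics are meaningful.
* The surface-map geometry is a stand-in; no claim is made that it matches
  any physical detector layout.
* Pearson r on a small held-out fold of saturated labels is a noisy
  statistic; the model-comparison experiment therefore aggregates over
  several seeds and tests direction, not magnitude.
* The DICOM codec reads Explicit VR Little Endian only — the syntax the
  package itself writes and the common export default of planning systems;
  implicit-VR archives must be transcoded first.
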