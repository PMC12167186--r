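---
title: "Methods: sequence-adaptive segmental quantification of parametric liver MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-adaptive segmental quantification of parametric liver MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

`mapquant` measures per-segment relaxation times on parametric maps (T1,
T2) by transferring a Couinaud label map, delineated once on a thin-slice
anatomical acquisition, through the scanner's physical coordinate frame. No
image registration is estimated: both volumes carry NIfTI affines `A`
mapping 0-based voxel indices to scanner world coordinates in mm, and the
transfer composes them, `v_src = A_src⁻¹ · A_map · v_map`. This is exact
when the patient does not move between acquisitions of the same session;
the one motion mode the pipeline addresses explicitly is through-plane
breathing displacement (see the NCC gate below). Its central assumption —
both acquisitions share one world frame — is also its main limitation:
gross inter-sequence motion or a re-localized patient invalidates the
transfer.

Parametric maps here are thick (8 mm), sparse (4 axial slices, 20–32 mm
apart), and in-plane coarse (1.41–2.19 mm) relative to the anatomical
source (3 mm slices, 1.19–1.56 mm pixels). Two design choices follow:

* **Slice matching.** Each map slice is matched to the source slice whose
  world center point — the affine image of the in-plane central voxel
  index, robust to oblique stacks — is nearest in Euclidean distance. Ties
  break to the lower source index for determinism. Map slices centered
  beyond the source stack are clamped to the terminal source slice with the
  distance recorded, rather than rejected: a clamped slice still usually
  intersects liver, and the downstream gates handle what does not. With
  3 mm source spacing and 32 mm map spacing, consecutive matched indices
  step by 10 or 11 (`round(32/3)`).
* **Slice-wise lookup.** A map voxel takes the label of the nearest source
  voxel *within the matched slice* (2D nearest-neighbor under the full 3D
  transform), honoring the slice-matched design; a free 3D nearest-voxel
  mode exists behind `mode = "volume"`. Labels are categorical, so
  nearest-neighbor is the only meaningful interpolant. Nearest means
  `floor(x + 0.5)` — half-voxel ties break deterministically upward. Map
  voxels leaving the source in-plane extent carry no ROI; vessel labels are
  excluded from every segmental ROI.

The segmental statistic is the volumetric ROI mean: all retained voxels of
a segment, pooled across the map's slices. The slice-weighted mean used by
manual protocols (per-slice ROI means weighted by ROI size) is recovered as
an identity, not implemented as a second mode. The median is reported
alongside. The total liver is the union of the *post-QC, passed* segmental
ROIs; voxels of omitted segments do not enter the total, keeping the two
levels consistent.

## The quality-control chain and its parameters

Five configurable measures (`qc_config()`), applied in a fixed order:
erosion → source-slice subselection → outlier removal → entropy gate →
minimum-size gate. The order was an open design choice; this one puts the
geometric corrections first so the value-based gates see the corrected
ROI, and the size gate last so the final count reflects every removal.

| parameter | default | grid | rationale |
|---|---|---|---|
| `erosion` | `none` | none / small / large | per-slice 2D erosion, 3×3 cross, 1 or 2 iterations; removes boundary voxels made ambiguous by the resolution gap. Outside the image counts as background. |
| `subselection`, `neighborhood` | off | off / 2 / 3 slices | breathing moves the liver cranio-caudally; among candidate source slices within the neighborhood, the one maximizing zero-normalized cross-correlation with the map slice inside the ROI (source intensities resampled bilinearly at the map voxels' world positions) replaces the geometric match. NCC ties break to the smallest offset, then the lower index; a zero-variance ROI keeps the geometric match. |
| `outlier`, `outlier_k` | `mad3`, k = 3 | off / mad3 | retain values within total-liver median ± k·MAD. MAD is the raw median absolute deviation (no 1.4826 consistency factor). The band is computed once per map over the union of all segmental ROIs, before any per-segment removal. If MAD = 0 (quantized or constant maps) everything is retained — the alternative (keep only the median value) would empty ROIs on integer-valued maps. |
| `entropy`, bins, threshold | `strict64` (64 bins, 4.5 bits) | off / 4 variants | Shannon entropy of the ROI intensity histogram over the sequence's full intensity range; high entropy flags noise and artifacts. The four variants pair {32, 64} bins with {strict, lenient} thresholds; 32-bin thresholds are scaled by log2(32)/log2(64) so strict/lenient mean the same fraction of the achievable maximum. The numeric thresholds (4.5 / 5.5 bits at 64 bins) are calibration parameters, not published constants, and are fully configurable. |
| `min_roi_size` | 50 voxels | 50 / 75 / 100 | measurements based on fewer analyzed voxels are omitted; a count exactly at the threshold passes ("minimally 50 analyzed voxels"). |

`qc_config_optimized()` ships the published best configuration: minimum 50
voxels, median ± 3·MAD removal, entropy detection on, no erosion, no
subselection.

Omission reasons are reported per segment × sequence:
`no_segment_in_source` (the label map contains no voxels of that segment on
any matched slice), `below_min_size`, `high_entropy`,
`emptied_by_outlier_removal`.

### Why MAD trimming attenuates extreme segments

A band at 3 raw MADs sits near 2.02 σ of a Gaussian ROI distribution, so
~4.3% of mass is always clipped. For a segment whose true value sits a
distance `d` from the total-liver median, the clip is asymmetric and pulls
the measured mean back toward the liver median by roughly `0.2·d` (small-d
linearization). This is an inherent property of the published outlier rule,
not an implementation artifact; it is benign when within-liver segmental
dispersion is small against the band, which is the clinical regime the rule
was optimized in. The phantom's truth model (below) respects that regime.

## Hyperparameter optimization

`grid_search()` evaluates every configuration of the grid (270 in full) on
a dataset of exams with reference measurements. Per configuration, ICC(1,1)
is computed per segment × sequence cell across exams (cells with fewer than
3 complete pairs are excluded; configurations with no valid cell are
skipped with a warning), and the score is

```
f = mean(ICC) − α · sd(ICC) + β · coverage,    α = β = 1 by default
```

with coverage = measurements performed / measurements available to the
reference reader. The linear form and unit weights are this package's
declared convention — the objective needed a concrete shape, and a linear
combination is the simplest function that is strictly monotone in all three
criteria (which is also what the Pareto-consistency property tests pin
down); both weights are arguments so other weightings can be restored.
Ranking is deterministic: score, then coverage, then configuration label.
The extraction stage (transfer, erosion, subselection) is cached per exam,
since the remaining gates only reprocess extracted voxel values.

## Statistics

* **ICC(1,1)**: one-way random, single-measure, absolute agreement, k = 2
  raters. Implemented from the explicit mean squares; CI and p-value from
  the standard F formulation (the p-value tests ICC = 0 via F — the
  alternative, a bootstrap test, was rejected for determinism). Perfect
  agreement (MSW = 0) reports a degenerate CI at the estimate; zero total
  variance reports 0 with a warning.
* **Deming regression**: closed-form errors-in-variables fit with variance
  ratio δ (default 1 = orthogonal, symmetric under axis swap). Zero
  variance on both axes is an error; a zero covariance with unequal
  variances returns the degenerate vertical/horizontal principal axis.
* **Spearman's ρ** with mid-rank ties and the asymptotic p-value
  (ties-safe); constant columns are flagged `NA` with a warning.
* **Paired Wilcoxon** (two-sided, normal approximation with continuity
  correction, so ties never abort) plus percentile-bootstrap 95% CIs:
  pairs are resampled for each arm's median, differences for the
  median-of-differences. The bootstrap is seeded and restores the caller's
  RNG state. All differences zero is reported as p = 1 with a degenerate
  flag.
* **Agreement categorization**: positive (both measured), negative (both
  absent), human-only — subdivided by the automated omission reason — and
  algorithm-only; counts always partition the table.

## The phantom: what it emulates, and what it does not

`generate_phantom()` renders a schematic liver — an ellipsoid (default
semi-axes 70 × 55 × 90 mm) split into 8 angular wedges, segment IV split
axially into IVa/IVb, two vessel tubes — on clinically realistic grids: an
80-slice, 3 mm anatomical stack at 1.19 mm pixels and 4-slice, 8 mm
parametric maps at 1.88 mm pixels, 32 mm apart (pixel spacings, slice
counts and spacings follow the published acquisition tables). Ground truth
is hierarchical: an exam-level baseline carries the population spread
(noncontrast T1 ~ N(835, 49.4²) ms, post-contrast T1 ~ N(518, 29.6²) ms,
T2 ~ N(37, 3.99²) ms), with small per-segment offsets (8 / 5 / 0.3 ms) on
top — within one liver, segments are nearly homogeneous, while patients
differ substantially; marginally the per-segment values keep the population
anchors (sd 50 / 30 / 4 ms). This split matters: with the entire population
spread placed between segments of one exam, the median ± 3·MAD rule would
truncate or empty extreme segments (see above), which is neither the
clinical regime nor a usable validation condition.

Maps and the anatomical volume share a smooth multiplicative texture field
(default amplitude 5%; a product of 20 mm-wavelength in-plane sinusoids
with z-dependent phases) standing in for parenchymal structure: it is
approximately mean-zero over any ROI, and its in-plane pattern decorrelates
over a few mm of z, which is what makes neighboring 3 mm slices
distinguishable by cross-correlation — without it, piecewise-constant
segments carry no alignment information at all. Voxel noise is Gaussian
with σ a fraction (default 2%) of the local true value. Artifact plumbing:
`inject_breathing_shift()` translates the source affine along world z while
leaving the data, so the declared geometry disagrees with the maps' anatomy
exactly as breathing does; `speckle_fraction` replaces random parenchymal
map voxels with the top of the intensity range; `noisy_segments` replaces
whole segments with full-range uniform noise (a high-entropy artifact).
The synthetic "manual" table is truth plus reader noise (5 ms for T1, 1 ms
for T2).

What the phantom does **not** emulate: anatomical shape (wedged ellipsoids,
not livers — nothing downstream depends on shape, only on labels, affines
and values), MR physics (no Bloch simulation, no Rician noise by default,
no B1/motion artifacts beyond the three plumbing hooks), in-plane motion,
and segmentation errors of the upstream network (the label map is an
input). Passing phantom tests therefore validates the geometry, gating and
statistics of the pipeline — not the segmentation quality or
artifact spectrum of real exams.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based throughout; the world frame is the NIfTI
  affine's frame, documented but never reoriented.
* NIfTI-1 stores the sform in float32; round trips preserve affines to
  ~1e-6 relative, and label maps round-trip bit-identically as int16.
* Nearest-voxel rounding is `floor(x + 0.5)`; NCC candidate ties prefer the
  smallest slice offset, then the lower index; slice-match distance ties
  prefer the lower source index.
* Bilinear resampling returns NA outside the source extent; NCC drops
  non-finite pairs and declares itself undefined (guarding to the matched
  slice) below 2 valid points or at zero variance.
* Determinism: the pipeline contains no randomness; the phantom and the
  bootstrap consume an explicit seed and restore the caller's RNG state.

## Problem sizes used in validation

The test-suite and the acceptance script run entirely on generated
phantoms: cohorts of 15–20 exams at the default geometry for recovery and
reliability checks, 20–40 single-sequence exams for breathing-recovery
trials, reduced-geometry suites of 4 exams for grid-search constructions,
and ≤ 64³ grids for the brute-force transfer oracle. These sizes were
chosen so each statistical check has comfortable power while a full
validation run completes in a few minutes on one CPU.
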