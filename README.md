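# mapquant

Sequence-adaptive segmental quantification of liver parametric MRI maps.

## The problem

Multiparametric liver MRI combines several quantitative sequences — T1
mapping before and after contrast, T2 mapping, and more — and clinical
assessment needs per-segment numbers from each of them. Drawing regions of
interest in all nine Couinaud segments on every sequence by hand takes
minutes per sequence per patient. `mapquant` automates the measurement
step: given one segmental label map delineated on a thin-slice anatomical
acquisition (a T1-weighted VIBE Dixon in-phase stack, labeled by any
segmentation method — the label map is a pluggable input), it transfers
those labels onto *arbitrary* co-acquired parametric maps and quantifies
them, with no map-specific tuning or training.

The package is aimed at imaging researchers who have co-registered NIfTI
volumes from one scanner session and want reproducible, quality-controlled
segmental relaxation-time tables plus the statistics to compare them
against a reference reader.

## The method

**Co-registration is purely geometric.** Both the anatomical stack and each
parametric map carry a 4×4 affine `A` mapping voxel indices to the
scanner's physical coordinate frame (mm). Each of the map's axial slices is
matched to the anatomical slice whose world-space center is nearest in
Euclidean distance; each map voxel `v` then receives the label of the
nearest source voxel at `A_src⁻¹ · A_map · v` within that matched slice.
Labels are categorical, so interpolation is nearest-neighbor; vessel labels
(portal and hepatic veins) are excluded from every segmental ROI.

**Quality control** is a configurable five-stage chain, applied in order:

1. *ROI erosion* (none/small/large): per-slice 2D erosion with a 3×3 cross,
   removing potentially ambiguous boundary voxels;
2. *source-slice subselection*: if the patient breathed between
   acquisitions, the geometrically matched slice is anatomically wrong; the
   neighboring source slice maximizing zero-normalized cross-correlation
   with the map slice inside the ROI is used instead;
3. *voxel outlier removal*: retain values within the total-liver
   median ± 3 · MAD (raw median absolute deviation);
4. *high-entropy detection*: omit ROIs whose intensity-histogram Shannon
   entropy exceeds a threshold (noise and artifacts);
5. *minimum ROI size*: omit measurements based on fewer than 50 analyzed
   voxels (a count equal to the threshold passes).

The segmental statistic is the volumetric ROI mean over all axial slices
containing the ROI, which equals the per-slice means weighted by ROI size.
Every omission carries a reason (`no_segment_in_source`, `below_min_size`,
`high_entropy`, `emptied_by_outlier_removal`).

**Reliability analysis** against a reference reader: one-way random,
single-measure intraclass correlation ICC(1,1) with F-based 95% CIs, Deming
errors-in-variables regression, Spearman's ρ, paired Wilcoxon with
percentile-bootstrap CIs, and a four-way agreement categorization
(both measured / both absent / human-only by omission reason /
algorithm-only).

**Hyperparameter optimization**: `grid_search()` scores every QC
configuration by `f = mean ICC − α·ICC SD + β·coverage` on a dataset with
reference measurements. The shipped preset `qc_config_optimized()` is the
published best configuration: minimum 50 voxels, median ± 3·MAD outlier
removal, entropy detection on.

**Synthetic phantoms**: `generate_phantom()` builds a full exam — 80-slice
3 mm anatomical stack, twelve-category label map, three 4-slice parametric
maps (8 mm thick, 32 mm apart) — from a wedged-ellipsoid liver with known
per-segment ground truth (noncontrast T1 ≈ 835 ms, post-contrast T1 ≈
518 ms, T2 ≈ 37 ms), optional noise, parenchymal texture, breathing shift,
outlier speckle and high-noise segments. Every pipeline stage is testable
without any patient data.

## Worked example

```r
library(mapquant)

ex  <- generate_phantom(phantom_spec(seed = 42))   # synthetic mpMRI exam
res <- run_exam(ex$source, ex$labels, ex$maps,
                config = qc_config_optimized(), exam_id = ex$exam_id)
res
#> <mq_exam_result 'phantom_42'> 27/27 segment measurements passed QC over 3 sequence(s)

head(res$measurements[, c("sequence_id", "segment", "mean_ms", "voxels", "reason")], 4)
#>   sequence_id segment  mean_ms voxels reason
#> 1      t1_pre       I 906.8792   1518     ok
#> 2      t1_pre      II 911.7637   1180     ok
#> 3      t1_pre     III 901.7618   1139     ok
#> 4      t1_pre     IVa 892.8018    804     ok

res$total
#>      exam_id sequence_id   mean_ms median_ms voxels
#> 1 phantom_42      t1_pre 899.33648 899.43773  10831
#> 2 phantom_42     t1_post 502.83146 502.71301  10884
#> 3 phantom_42          t2  38.51814  38.51985  10798
```

Each `measurements` row is one segment on one parametric map: the
volumetric ROI mean in ms, the number of analyzed voxels after quality
control, and either `ok` or the omission reason. `total` pools the passed
segmental ROIs into a per-sequence total-liver measurement. Comparing
against the phantom's ground truth:

```r
m <- merge(res$measurements, ex$manifest, by = c("segment", "sequence_id"))
max(abs(m$mean_ms - m$true_value_ms) / m$true_value_ms)
#> [1] 0.005486132          # all segments recovered within 0.6%
```

A thin command-line front end covers the same pipeline on files:

```sh
exec/mapquant phantom --seed 1 --out exam1/
exec/mapquant run --source exam1/dixon_ip.nii.gz --labels exam1/labels.nii.gz \
    --map exam1/t1_pre.nii.gz --map exam1/t2.nii.gz --out results.csv
```

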