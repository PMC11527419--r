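---
title: "Methods: GCSS parcellation and pattern similarity for auditory statistical learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GCSS parcellation and pattern similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slgcss)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, and the numerical and design choices that were
genuinely open — so that a maintainer can tell which behaviour is
principled and which is a convention that could defensibly have gone
another way.

## The analysis problem

In an auditory statistical-learning (SL) paradigm, listeners hear
*structured* sequences — built from fixed triplets of syllables or tones
that always co-occur — and *random* sequences of the same 12 tokens with no
repeating structure. Each subject contributes one 3D contrast volume per
task (structured > random, z or T units) on a common voxel grid. Group
questions are then asked not of a voxelwise group mean, which washes out
when individual activations are spatially heterogeneous (as in children),
but of *subject overlap*: where do enough individual subjects each show
their own significant effect?

All volumes entering a group stage must share one grid (shape, voxel size,
affine, to 1e-3); the package refuses mismatches rather than resampling,
because silent resampling changes the statistics being summed. Template
identity (e.g. which MNI variant) is treated as opaque metadata.

## Task generation

Structured blocks draw a triplet order by repeated random choice with the
single rule that no triplet follows itself, each of the 4 triplets
appearing exactly `reps_per_triplet` (default 8) times — 96 tokens, 32
triplet runs. Random blocks are built token-by-token, rejecting any token
that would repeat an already-seen ordered trigram (overlapping windows),
with bounded restarts (10,000). Two readings of the no-repeated-trigram
rule were possible — per block or per run; we implement it **per block**,
which matches the block-wise description of the sequences, and note that a
12-token alphabet at length 96 leaves the constraint easily satisfiable
either way. Timing is exact: onsets advance by `stim_ms + isi_ms`
(460 + 20 = 480 ms), so a triplet spans 1,440 ms. Rest-block duration is
a parameter (default 0) because only block-internal onsets matter to the
analyses here; rest affects only block start bookkeeping.

## Behavioral scoring

A press is a valid response to the *earliest not-yet-matched* target whose
window (default 0–960 ms after onset, inclusive) contains it; each press
matches at most one target and each target keeps only its first press.
This rule is deterministic under any overlap of windows (targets in
structured blocks are 1,440 ms apart, so overlap is rare but possible
with random-block targets).

The false-alarm denominator is not dictated by the A′ formula itself; we
count the **number of non-target stimuli** as opportunities, assign each
unmatched press to the most recent non-target onset, and count *distinct*
alarmed onsets — symmetric with the hit definition and guaranteed to keep
the rate in [0, 1] even for button-mashing responders.

A′ follows the piecewise formula: for fa < hit,
A′ = 1/2 + ((hit − fa)(1 + hit − fa)) / (4·hit·(1 − fa)); for fa > hit the
mirrored branch; equal rates give 0.5, the common limit of both branches.
The two branches satisfy A′(h, f) + A′(f, h) = 1, which the test suite
checks on a grid. Pooled-across-blocks rates are the default unit for a
condition-level A′ (per-block values are also emitted); pooling uses more
trials per estimate, which matters with as few as 8 targets per block.

RTs are summarized raw and under the natural log (a log-mean near 6
corresponds to ~400 ms, which is the right scale for millisecond RTs).
Conditions with fewer than 6 valid presses are excluded from behavioral
contrasts only — poor behavioral performance does not remove a subject
from imaging, since SL is implicit. The paired contrast is the classical
paired t (df = n − 1), computed in closed form so degenerate inputs
(all-zero differences → t = 0; constant nonzero differences → undefined,
flagged) return sentinels instead of errors; it is cross-checked against
`stats::t.test` in the tests. Mean-FD exclusion removes subjects above the
group mean + 1.5 SD, both moments computed before any exclusion.

## GCSS parcellation

Pipeline: threshold each subject map at z > 2.326 (one-tailed p < 0.01)
and binarize inside the mask → sum to a probability map → smooth (6 mm
FWHM Gaussian, zero-padded separable convolution) → zero voxels below
`fraction × n_subjects` (default 0.6) → find local maxima → grow watershed
basins.

Numerical choices worth recording:

* **Connectivity is 26** for maxima, basins, and growth; unstated in the
  field's verbal descriptions but the common volumetric convention.
* **The watershed is the hill-climbing variant**: every positive voxel
  follows steepest ascent among its 26 neighbours (ties broken toward the
  smaller linear index) to its governing maximum; each retained peak's
  basin is one parcel. This is exactly equivalent to seeded watershed by
  descent on the negated field for fields without plateaus, and it admits
  an independent per-voxel brute-force oracle against which the
  implementation is tested voxel-for-voxel on random fields. On equal
  values the tie rule walks toward smaller indices, which terminates and
  keeps the assignment deterministic; interior plateau voxels that reach
  no strict maximum remain unassigned, a measure-zero situation for
  smoothed probability maps.
* **Minimum peak separation** is 3 voxels (Euclidean, voxel units
  authoritative; a flag computes it in mm instead — at 2.5 mm voxels the
  two readings genuinely differ, 7.5 mm vs 10 mm). Among maxima closer
  than that, the highest survives (ties to smaller index), and the
  **basin of a suppressed maximum is merged into the peak that suppressed
  it**, so shoulder bumps do not shed voxels from their parent parcel.
* **Two different uses of "60%"** are kept distinct: the smoothed-map
  criterion (`fraction × n` on the counts scale, applied before
  segmentation — smoothing approximately preserves that scale) and the
  post-hoc per-parcel subject count, recomputed from the *unsmoothed*
  binary maps as "≥ 1 suprathreshold voxel inside the parcel". Both are
  reported.
* Parcel effect size is the one-sample Cohen's d of per-subject parcel
  means, with power from the noncentral-t (via `stats::power.t.test`,
  cross-checked against the explicit tail formula); at d = 0.73 and
  n = 27 this yields ~0.95–0.96. A constant-zero signal gives d = 0 by
  convention; a constant nonzero one is undefined and flagged.

## Conjunction and block consistency

Conjunction is the voxelwise AND of one subject's two binarized task maps,
aggregated by the unchanged GCSS pipeline. For block-wise consistency, the
voxel set is fixed **once per (subject, parcel)** as the top 10% of the
subject's overall source-task T-map inside the parcel, and that same set
is reused for every within- and between-task block comparison — keeping
all comparisons on identical supports, at the cost of mildly favouring the
source task's signal-bearing voxels. Between-task rows pair equal block
indices only. Correlations are computed per subject and aggregated by a
one-sample t across subjects; no formal within-vs-between test is offered,
as the two are not computed on exchangeable units.

## Local pattern similarity

Parcel-level similarity is the per-subject Pearson correlation of the two
unsmoothed contrast maps over the parcel's voxels, with a group one-sample
t against zero. The searchlight assigns each in-mask center the
correlation over the in-mask voxels of the Euclidean sphere of radius 3
voxels (center included; 123 voxels when unclipped). Boundary spheres use
the voxels available; centers with fewer than 3 usable voxels or zero
variance are **undefined (NA), never zero-filled** — absence of evidence
is not evidence of zero similarity — and undefined centers count as
sub-threshold at binarization. "Normalization" of Fisher-transformed maps
is read as z-scoring each subject's map over its defined in-mask voxels
(no reference distribution being stated, the within-map standardization is
the one that makes the z = 2.3 threshold meaningful per subject); a flag
disables it. |r| = 1 is clipped to 1 − 1e-7 before atanh. The LPSA
threshold 2.3 and the subject-map threshold 2.326 are deliberately kept as
distinct constants. The searchlight core is compiled (Rcpp) because it is
the only O(voxels × sphere) inner loop in the package; a brute-force R
enumeration serves as its oracle in the tests.

## The synthetic cohort generator

The generator produces what the analyses consume, with full ground truth:

* **Noise**: white Gaussian noise smoothed at 6 mm FWHM and rescaled by
  the kernel's L2 norm, so the field has unit variance in the mask
  interior and P(z > 2.326) ≈ 0.01 holds there by construction (the
  calibration is verified in the tests; boundary voxels are attenuated by
  the zero padding, which is why calibration is assessed on an eroded
  mask).
* **Regions** are flat-amplitude balls (default radius 10 mm, peak z = 4)
  centered in world mm, with per-subject integer-voxel jitter (rounded
  N(0, 0.5 voxels), i.e. shifts essentially within one voxel). Roles:
  active in both tasks, one task only, or carrying zero-mean voxel
  patterns in both tasks with a target negative cross-task correlation
  (default −0.5), built by mixing a shared latent pattern with independent
  noise so the correlation holds in expectation.
* **Participation is an exact count**: `round(fraction × n)` subjects are
  sampled without replacement. "Active in 70% of subjects" is read
  literally; Bernoulli participation at n = 27 would make the realized
  fraction straddle the 60% criterion in a substantial share of cohorts,
  turning a property of the method into a coin flip of the generator.
* **Responders** press after targets with probability `p_hit` (Normal RT
  truncated to the window) and after non-targets with probability `p_fa`
  (uniform lag); a learning slope shifts the structured-condition RT mean
  per block.
* Defaults — 27 subjects, 32×38×32 grid at 2.5 mm, ellipsoid mask — mirror
  a realistic pediatric cohort and acquisition resolution while keeping a
  full simulate-and-analyse cycle under a second.

What the generator does **not** emulate: hemodynamics and time-series
structure, motion artifacts, first-level GLM estimation, non-stationary or
heavy-tailed noise, anatomically shaped regions, and between-subject
amplitude variability beyond participation and jitter. Passing recovery
and calibration tests therefore demonstrates that the *pipeline* is
correct and calibrated under its stated noise model — not that real
developmental fMRI data satisfy that model.

## Validation scales

The test suite validates the watershed against an exhaustive
steepest-ascent oracle on fifty 20³ random fields; the searchlight against
brute-force sphere correlations; planted-region recovery (participation
0.7 vs 0.3, fifty replicates each of the default 27-subject cohort) at the
60% criterion; emptiness of conjunction and searchlight aggregations on
fifty no-shared-structure cohorts together with the calibration of the
group similarity t; and the sign and significance of recovered
anti-correlated patterns. These sizes were chosen to give binomially
meaningful pass bands while keeping the full suite in the minutes range on
one core.

## Known limitations

* No resampling or registration: inputs must already share a grid.
* The watershed leaves interior plateau voxels unassigned rather than
  splitting plateaus; irrelevant for smoothed probability maps, visible
  on artificial piecewise-constant fields.
* The suppressed-maximum merge assumes the suppressed basin is contiguous
  with its retaining peak's basin, which holds for smoothed fields but is
  not enforced.
* Behavioral scoring assumes block-local press timestamps; cross-block
  presses are out of scope.
* The FD exclusion rule uses the pre-exclusion group moments once; it is
  not iterated.
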