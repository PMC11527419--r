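# slgcss

Group-constrained subject-specific (GCSS) parcellation and pattern
similarity analysis for auditory statistical-learning (SL) fMRI studies,
with a fully specified task generator, behavioral scorer, and synthetic
ground-truth cohort simulator.

## Who this is for

Developmental cognitive-neuroscience labs running auditory SL experiments
in which listeners hear *structured* sequences (hidden triplets that always
co-occur) and *random* sequences of the same tokens, while per-subject
structured > random contrast volumes are collected. Because individual
activation in such paradigms — particularly in children — is spatially
heterogeneous, fixed-effects group maps can miss effects that are robust
within subjects. The GCSS approach asks instead: *where do a criterion
fraction of subjects each show their own significant activation?*

## The method

**GCSS parcellation.** Each subject's contrast map is thresholded at
z > 2.326 (one-tailed p < 0.01) and binarized inside the brain mask. The
binary maps are summed into a probability map P(v) = number of active
subjects at voxel v, smoothed with a 6 mm FWHM Gaussian kernel, and zeroed
where P < 0.6·N (the 60% overlap criterion). The surviving field is
segmented into parcels by a watershed: every positive voxel follows
steepest 26-neighbour ascent to its governing local maximum (retained
maxima must be ≥ 3 voxels apart), and each basin becomes one parcel,
stopping at zero-valued voxels and local minima. Per parcel we report the
number of subjects with ≥ 1 suprathreshold voxel inside it, the one-sample
Cohen's *d* of the subject-mean contrast, and the noncentral-t power of the
corresponding one-sample t test.

**Conjunction.** A subject's conjunction map is the voxelwise AND of its
two tasks' binarized maps; conjunction maps feed the identical GCSS
pipeline to locate regions jointly active across tasks and subjects.

**Local pattern similarity (LPSA).** Per subject, Pearson correlation
between the two tasks' unsmoothed contrast maps — over each parcel's
voxels, or in a radius-3-voxel searchlight sphere centered on every in-mask
voxel. Searchlight maps are Fisher-transformed (atanh), z-scored over
defined voxels, thresholded at z = 2.3, and aggregated with the same GCSS
pipeline. Group inference is a one-sample t of per-subject r against 0.

**Task design and behavior.** Structured blocks concatenate 4 triplets × 8
repetitions (96 tokens, no identical triplets adjacent); random blocks are
96 tokens in which no ordered trigram repeats. Stimuli last 460 ms with a
20 ms gap, so a triplet spans 1,440 ms. Button presses are scored against a
0–960 ms valid-response window (earliest-unmatched-target rule), giving hit
and false-alarm rates, the piecewise A′ sensitivity index, and (log-)RT
summaries; subjects with < 6 valid presses are excluded per condition, and
mean-FD outliers (> group mean + 1.5 SD) are flagged for imaging exclusion.

## Worked example

Simulate a 27-subject cohort on a 32×38×32 grid of 2.5 mm voxels with one
planted region (10 mm radius at the mask center) that is active in both
tasks for 80% of subjects but carries *anti-correlated* fine-grained
patterns across tasks (target pattern correlation −0.5):

```r
library(slgcss)

regions <- rbind(
  synth_region(c(0, 0, 0), radius_mm = 10, role = "shared",
               peak_effect_z = 4, participation = 0.8),
  synth_region(c(0, 0, 0), radius_mm = 10, role = "anticorrelated_pattern",
               peak_effect_z = 2, participation = 1))
truth  <- synthetic_truth(regions, anticorr_r = -0.5)
cohort <- simulate_contrast_maps(truth, n_subjects = 27, seed = 42)

binmaps <- lapply(cohort$vols$syllable, binarize, mask = cohort$mask)
parcels <- gcss_parcellate(binmaps, fwhm_mm = 6, fraction = 0.6,
                           min_separation = 3)
parcels <- parcel_effect_size(parcels, cohort$vols$syllable)
parcels$parcels
#>   parcel_id peak_i peak_j peak_k n_voxels n_overlap_subjects overlap_fraction  cohen_d power
#> 1         1     17     20     17       54                 27                1 2.119493     1

parcel_set_similarity(parcels, cohort$vols$syllable, cohort$vols$tone)
#>   parcel_id     mean_r    t_stat df p_two_tailed n_subjects
#> 1         1 -0.4916555 -22.87754 26 9.469478e-19         27

ground_truth_report(cohort, parcels)
#>   region                   role  hit best_dice best_parcel
#> 1      1                 shared TRUE 0.3233533           1
#> 2      2 anticorrelated_pattern TRUE 0.3233533           1
```

Reading the output: the syllable-task GCSS finds one parcel whose peak sits
inside the planted region (`hit = TRUE`); all 27 subjects overlap it and
the subject-mean contrast is large (d ≈ 2.1, power 1 — the planted effect
is strong by construction). The pattern similarity between tasks inside
that parcel is strongly negative (mean r ≈ −0.49, p ≪ 0.001), recovering
the planted anti-correlation: a region can be *active* in both tasks yet
encode them with unrelated or opposed voxel patterns. The Dice of 0.32
reflects that the watershed parcel covers only the suprathreshold core of
the 10 mm ball.

An end-to-end run (simulate → behavior → GCSS → conjunction → LPSA →
recovery report, with a manifest) is `run_pipeline(pipeline_config())`, or
from a shell: `Rscript inst/cli/slgcss.R all --seed 1 --out out/`.

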