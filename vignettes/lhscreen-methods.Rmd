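---
title: "Methods: anatomical overlap and optogenetic behaviour analysis for lateral horn screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomical overlap and optogenetic behaviour analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhscreen)
```

## The problem

The lateral horn (LH) is the higher olfactory neuropil of the fly brain that
mediates innate odour responses. Screens of intersectional (split-GAL4) driver
lines targeting LH cell types produce two kinds of quantitative data:

1. **Anatomy.** Confocal stacks of labelled neurons, registered to a template
   brain (e.g. JFRC2013) so that voxelwise comparison across brains is
   meaningful. The question is which cell types' arbors occupy the same
   territory — a proxy for potential connectivity.
2. **Behaviour.** Optogenetic activation read out in a four-quadrant choice
   arena (valence), a Flybowl (locomotion under whole-field stimulation) and a
   tethered-flight rig (wingbeat kinematics), screened across many lines
   against an enhancerless split-GAL4 control.

This package implements that analysis chain end to end, plus synthetic-data
generators with exact ground truth so every stage can be validated without any
imaging data.

## Mask construction

A cell type's binary mask is built from `n = 3` registered replicate stacks by

overlay → contrast enhancement → Gaussian blur (σ = 1) → Otsu auto-threshold

(`make_mask()`). Choices the recipe leaves open, fixed here and recorded in
each mask's provenance attribute:

* **Overlay** is the voxelwise maximum by default (`overlay = "max"`); the sum
  is available. Max is robust to lines imaged with different replicate counts.
* **Contrast enhancement** is a percentile clip and linear rescale to [0, 1].
  The clipped fraction defaults to 0.0035 (0.35%), the common interactive
  display default; the clip bounds are the type-7 sample quantiles.
* **Blur** is separable Gaussian filtering with σ in voxel units, isotropic in
  index space (matching a pixel-σ convention), kernel truncated at
  `ceiling(3σ)` with edge replication. A micrometre-specified anisotropic σ is
  available via `sigma_um`.
* **Otsu** maximises between-class variance over 256 equal-width bins of the
  intensity range; ties break toward the lower threshold; the mask keeps
  voxels **strictly above** the threshold. Constant images raise an error
  rather than silently producing empty masks.
* The stage order (overlay, enhance, blur, threshold) follows the order the
  steps are usually described in; it is a convention of this package, recorded
  in provenance so runs are reproducible.

A property worth knowing: after blurring, boundary voxels at high-curvature
surfaces (branch tips, rod corners) fall below any mid-range threshold, so the
recovered mask is not a strict superset of a thin ground-truth shape — it
agrees with it to ≥99% of voxels with all extras inside the blur support. The
overlap scores that matter downstream are insensitive to this sub-voxel
surface effect (see the recovery experiment below).

## Overlap scores

For two non-empty masks on one grid, `P1 = 100·|A∩B|/|A|` is the percentage of
A inside B, `P2` the reverse, and the reported score is their mean
(`overlap_score()`; max and min are computed alongside and behave similarly).
Denominators are voxel counts: all masks share one grid, so physical volume
would differ only by a constant factor.

* `pairwise_matrix()` assembles score matrices; with one mask set and the mean
  rule the matrix is symmetric with diagonal 100. The −1 "self" sentinel seen
  on some heatmaps is applied only at render time (`autoplot()`); the stored
  matrix always keeps true values.
* `classify_interactions()` flags a *significant potential interaction* where
  the score **strictly exceeds 15%**, the cutoff validated against double
  labelling, and summarises per row the fraction of cell types with at least
  one partner. Overlap never proves synapses; it bounds where connections are
  plausible.
* `cluster_matrix()` orders rows/columns by agglomerative clustering of the
  score vectors (Euclidean distance, complete linkage, no standardisation).
  Exact leaf order is display convention, not a scientific claim; tests
  therefore check the partition structure, not leaf sequences.
* `axon_dendrite_relation()` regresses one score set on another over all
  off-diagonal pairs (OLS) and reports R²; it answers whether neurons with
  overlapping dendrites also co-project their axons.

`average_modality()` and `modality_occupancy()` build modality-averaged input
maps: one exemplar mask per input neuron of a modality, voxelwise mean,
restricted to a neuropil region. "Ventral vs dorsal" sub-regions are defined
by a plane through the region centroid along a named axis
(`split_region_at_centroid()`) — an operationalisation of what is otherwise
shown qualitatively, not a published quantity.

## Quadrant assay

Quadrants are angular sectors around the arena centre with Q2/Q3 one diagonal
pair and Q1/Q4 the other. The preference index per frame is

PI = (flies in Q2 and Q3 − flies in Q1 and Q4) / total,

computed per frame (optional binning can be layered on; per-frame is the
default because nothing in the formula requires smoothing). During each
light-ON epoch, labels are normalised so the illuminated pair maps to Q2/Q3 —
both epochs then contribute with a consistent sign and positive PI means
attraction (`relabel_on = TRUE`; the raw geometric convention is available).
The **single-value PI** averages the PI over the final 5 s of each of the two
ON epochs, equally weighted.

Locomotion deltas (`delta_metric()`) compare the first 5 s of stimulation with
the 5 s immediately before onset, per fly, normalised by the
**pre-stimulation** mean — the denominator the delta definition leaves
ambiguous, so it is flagged in the output metadata. Only flies that stay in
the illuminated quadrants for the whole stimulation window are included;
stationary flies (zero pre-mean) are excluded with a reason. Forward
locomotion is path length per second in camera pixels (1 px ≈ 0.12 mm),
turning is absolute heading change of the centroid displacement with
sub-noise steps (< 0.5 px) contributing zero, and distance-from-centre is in
pixels. Tracking gaps up to 3 frames are linearly interpolated
(`interpolate_track_gaps()`); longer gaps drop the fly from gated windows.
Upwind/downwind movement is computed only if a wind-direction map is supplied
with the schedule; the standard schedule format carries none, so it is
omitted rather than guessed.

`flybowl_locomotion()` reports per-fly mean pixel speed over one of the three
5 s whole-field stimulations of increasing intensity (3.59, 11.88,
25.2 µW/mm²), the strongest by default; each fly is an experimental unit.

## Tethered flight

Yaw is left-minus-right wingbeat amplitude; thrust is their sum. Per trial
(10 s at 1 kHz, LED onset at 5 s for 500 ms), the mean of the 100 ms before
onset is subtracted; stim and no-stim trials of each fly are averaged
separately over the six blocks and the response is their difference
(`fly_response()`), so a response trace has exactly zero baseline mean by
construction. Flies are weighted equally in the group mean (pooling trials
would weight flies by trial survival, which is not what a per-animal claim
needs). |yaw| is rectified **after** per-trial baseline subtraction,
mirroring how absolute turning is plotted. Trials whose wingbeat frequency
drops below a floor (default 120 Hz — the fly stopped flying) are excluded
whole.

`per_timepoint_test()` compares two groups' per-fly responses sample by
sample with a two-sided Wilcoxon rank-sum test at α = 0.05 and **no
multiplicity correction** — these marks annotate stretches of a trace, they
are not a familywise claim. The exact null distribution is used for group
sizes ≤ 10 without ties (for 6 vs 6 the smallest attainable two-sided level
below 0.05 is ≈ 0.041, which is what a calibrated null rate converges to);
larger groups use the normal approximation with tie and continuity
correction. Tests run at native sampling by default, with a decimation option
for long sessions.

## Screening statistics

The screen chain (`screen_lines()`) is: Brown–Forsythe/Levene check (median
centres by default — the robust variant; mean centres available since the
original call is not recorded), Kruskal–Wallis with tie correction, then
Dunn's post-hoc z for each line against the control on pooled ranks,

z = (R̄ᵢ − R̄₀) / √[(N(N+1)/12 − Σ(t³−t)/(12(N−1))) (1/nᵢ + 1/n₀)],

two-sided p-values throughout (the screen must catch attraction and aversion).
The primary screen adjusts by Benjamini–Hochberg with FDR controlled at 10%
and declares significance at adjusted p < 0.05 — both the level and the
cutoff are parameters, reported side by side, because the procedure is stated
with both numbers; replication experiments use Bonferroni.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its design object (which embeds the
seed) and returns its ground truth alongside the data; recovery tests never
re-derive parameters from file names.

* **Arbors** (`generate_replicate_stacks()`): a union of capsule-shaped
  branches traced by reflecting random walks on a 64×64×32 grid at
  0.56×0.56×1.0 µm (the 20x acquisition voxel size, spatially scaled down).
  Replicate-to-replicate jitter is a rigid translation — residual
  registration error — applied in whole voxels so the displaced ground-truth
  voxel set stays exact; the continuous Gaussian draws (default SD one x/y
  voxel, a modelling choice since registration error is uncharacterised) are
  kept as metadata. Foreground/background intensities 1.0/0.1 with Gaussian
  noise SD 0.02 give the clearly bimodal histograms this pipeline is used on.
  No optics are simulated (no PSF, no channel bleed-through).
* **Designed mask pairs** (`generate_mask_pair()`): two compact rods laid
  along a shared raster order so that |A∩B| = round(f·|A|) **exactly**; the
  pipeline-recovery experiment renders them as replicate stacks without
  jitter, because jitter would change the true intersection rather than the
  measurement of it.
* **Quadrant walker** (`generate_quadrant_trial()`): which diagonal pair a
  fly occupies is an explicit two-state Markov chain (per-frame enter/exit
  probabilities p₀(1±bias)), with a reflecting Gaussian walk inside the
  current quadrant. A direction-biased walk has no closed-form occupancy;
  making the region process itself the chain keeps the designed stationary
  occupancy analytic — P(lit) = p_enter/(p_enter+p_exit), so the stationary
  ON-epoch PI equals the bias. The cost is realism in within-arena paths
  (flies teleport across a boundary on a switch event); occupancy statistics,
  which is what the PI uses, are exact.
* **Flight sessions** (`generate_flight_session()`): randomly interleaved
  trials per block (visual × stim), designed step effects during the LED
  window decaying exponentially after offset, white measurement noise plus a
  slow per-trial offset that the baseline subtraction must remove. Real
  wingbeat traces are autocorrelated; white noise makes per-timepoint tests
  independent across samples, which the calibration tests rely on — a
  simplification to keep the null exactly known, not a claim about rigs.

Consequently, passing tests demonstrate correctness of the computations and
calibration of the statistics under these models; they do not certify
performance on real confocal stacks or tracker output.

## Validation scales

The validation suite and the results script run, per decisions made for
statistical resolution: exact-oracle overlap comparison on 50 designed pairs
(24×24×16 grids, where brute-force per-voxel counting is itself fast);
pipeline recovery of f ∈ {0.1, 0.3, 0.5, 0.8} over 20 seeds each on the
default grid; Otsu-vs-exhaustive agreement on 100 images; a 100-replicate
global-null screen of 50 lines × 10 replicates; and flight sessions at the
full 1 kHz / 6-block structure with 6 flies per group.

## Known limitations

* No image registration or bridging between template spaces: inputs must
  already share a grid, and grid mismatches are hard errors.
* Compartment (axon/dendrite/membrane) is input metadata; the package does
  not split arbors.
* The NRRD reader covers the subset this package writes (3D, little-endian
  raw/gzip, double/uint8), not the full format zoo.
* Overlap scores are proximity proxies; electron-microscopy validation of
  individual pairs is out of scope.
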