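---
title: "Methods: dual-area imaging analysis in DualScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-area imaging analysis in DualScope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DualScope)
```

## The analysis problem

A rotating mirror pair placed in the post-objective space of a two-photon
microscope switches the field of view between two distant cortical areas
(for mouse motor cortex: the rostral and caudal forelimb areas, RFA and
CFA) quickly enough to image both quasi-simultaneously. DualScope covers
the full analysis chain around such recordings:

1. **Device geometry**: where the FOV can go, how fast two fields can be
   alternated, and how many pixels per second the configuration yields.
2. **Resolution characterization**: lateral and axial FWHM from bead
   z-stacks.
3. **Trace processing**: percentile baselines, zero-phase event
   filtering, peak detection, down-sampling, clock resampling, movement
   masking.
4. **ROI selection** by footprint size and eccentricity.
5. **Pairwise correlation analyses**, including soma-axon bouton
   matching across areas.
6. **Behavior**: lever-pull trial detection, metrics, trial selection.
7. **Population covariation**: do the two areas' trial-to-trial
   population activity patterns covary?

## Geometry model

The FOV center is displaced from the device axis by the inter-mirror
distance `d_mm` (2.5 mm by default); rotating the device by `theta` moves
it along a circle of that radius, so two positions are separated by
`d_mm * 2 * sin(theta / 2)`. The FOV itself is a square of side
`fov_side` that **rotates with the device**, so the corner can point
radially: the observable region is an annulus of radii
`d_mm ± fov_side * sqrt(2) / 2`. With the 1 mm default FOV this gives a
maximum observable (edge-to-edge) distance of 2 × 3.207 ≈ 6.4 mm. Per-FOV
sizes other than the configured square are deliberately not guessed;
edge-to-edge distances at intermediate angles are therefore reported only
as a function of the explicit `fovSide`. A "longest stitched line"
quantity is not computed: its geometric construction is ambiguous (an
annulus chord tangent to the inner circle through the corner-extended
bounds does not reproduce a unique value), and nothing downstream needs
it.

Dual-field timing composes one scan per field plus one rotation per
switch: `rate = 1 / (2 * (scan + rotation))`. Rotation durations are
tabulated by angle (43 ms at 60°, 80 ms at 180° by default) and linearly
interpolated between tabulated angles; extrapolating outside the table is
an error rather than a guess.

## PSF characterization

Bead stacks arrive as five repeat frames per focal plane, which are
averaged (`averagePlaneRepeats`). Lateral profiles are single lines along
X and Y through the intensity-weighted bead centroid in the plane of
maximum mean intensity. Axial profiles come from XZ and YZ sections
through the centroid, sampled by bilinear interpolation along the
section's principal axis (the direction the bead is elongated in), at a
uniform spacing of half the smaller voxel dimension — axial sections are
anisotropic (0.249 µm laterally vs 0.5 µm in z by default), so resampling
is required before a fit.

Numerical choices:

* **Background** is the median of the volume's border voxels; a volume
  whose smoothed maximum does not exceed eight border-MADs above
  background is rejected as bead-free.
* **Center and orientation** are estimated on a 3-voxel box-smoothed
  copy of the data (and with squared weights above a 20%-of-max
  threshold for the section moments); otherwise, at low SNR, stray noise
  voxels dominate the second moments and tilt the sampling line, which
  biases the axial FWHM far more than it biases a 1-D fit. Profiles are
  always extracted from the raw data.
* **Gaussian fits** (offset + amplitude + center + sigma) use
  Levenberg-Marquardt least squares, initialized at the profile argmax,
  the second-moment sigma, and the profile minimum as offset. FWHM is
  `2 * sqrt(2 * ln 2) * sigma`. The axial estimate is the arithmetic
  mean of the XZ- and YZ-section fits.

Synthetic beads at SNR 20 are recovered with a median per-axis error
under 1%; at SNR 5 the median stays under 10%.

## Trace processing

* ΔF/F uses the 8th percentile of each unit's **whole** acquired series
  as baseline (linear interpolation between order statistics); units with
  a non-positive baseline are excluded, not patched.
* Inferred spike events (deconvolved transient amplitudes) are smoothed
  with a unit-sum Gaussian kernel — 100 ms s.d. for soma-soma analyses,
  500 ms for soma-axon — truncated at ±4σ and applied in a single
  symmetric pass with reflected edges. For a symmetric FIR kernel this
  is exactly zero-phase, the same contract as forward-backward
  filtering: an impulse stays centered and interior mass is conserved to
  1e-6.
* Peak events are strict local maxima above 2 s.d. of the filtered
  trace, with the s.d. computed over the analyzed (masked) period; the
  retention rule for pairwise analyses keeps units with **more than** 10
  peaks. The s.d. is taken on the filtered trace because that is the
  signal the peak finder scans.
* Down-sampling skips frames (decimation without anti-aliasing),
  matching how lower frame rates arise from subsampled acquisition.
* Resampling onto the interleaved dual-field clock (two 5.4 Hz fields
  offset by half a period → 10.8 Hz) is linear interpolation;
  extrapolation outside the recorded span is an error.
* Movement masking drops frames from 1 s before to 1 s after any lever
  movement and concatenates the rest, returning the kept-frame index map
  so correlations are computed on the concatenation.

## ROI selection

Somatic components are kept when footprint area exceeds 50 µm² **and**
moment-ellipse eccentricity exceeds 0.5, both as strict inequalities (the
keep-elongated rule removes extracted apical dendrites in L2/3 planes; it
is counterintuitive but applied exactly as stated, and the comparator is
configurable). Because extracted footprints are soft, the area counts
pixels above 10% of the footprint's maximum weight; eccentricity uses
weighted image moments for stability, with a binary-mask variant for
testing.

## Soma-axon matching

Both event sets are filtered at 500 ms, units below the peak-count rule
are dropped, and every retained soma is correlated with every retained
bouton. For each soma, the CC distribution over all boutons yields its
mean and s.d.; the z-score of a candidate CC is
`(cc - mean) / sd` — the distribution mean is near zero and is
subtracted, so a 0.78 top CC over a 0.12-s.d. distribution scores
6.5 s.d. Candidate matches use an absolute CC criterion (default 0.6) or
an optional z criterion. Undefined CCs (zero-variance units) are excluded
from distribution statistics, never imputed.

## Population covariation

The core question is whether trial-to-trial fluctuations of population
activity covary between areas:

1. Events resampled at 10.8 Hz are tested per neuron: activity pooled
   over the movement window (−5 to +20 resampled frames around pull
   onset, i.e. −0.46 to +1.85 s) versus the rest window (−25 to −10
   frames), one-sided Wilcoxon rank-sum at α = 0.05 (one-sided because
   the criterion is "larger during movement"; a two-sided flag exists).
2. Movement-related neurons are z-scored over the **full session**
   (z-scoring precedes trial realignment), movement windows are sliced
   per selected trial and averaged over time: one cells × trials matrix
   per area.
3. Trial similarity is the Pearson CC between trial population vectors
   (sensitive only to the angle between patterns; a negative squared
   Euclidean variant also sees scaling).
4. **Affinity propagation** clusters the trials. The preference is the
   median of the **off-diagonal** similarities (the diagonal is the
   preference slot itself); percentile variants (1st/10th/30th/70th) are
   supported and cluster count is non-increasing as the percentile
   drops. Messages are damped at 0.9; convergence requires 100
   iterations with an unchanged exemplar set within a 1000-iteration
   cap, and exact ties break toward the lowest index, making the result
   deterministic. A non-converged run returns its state with a warning
   rather than failing.
5. The **cross-area intra-cluster CC** groups trials by one area's
   clusters and averages the mean pairwise CC of the *other* area's
   vectors within each non-singleton cluster. The null permutes the
   trial-to-cluster assignment map 1000 times under a recorded seed and
   reports the mean over permutations ("shuffling the trial labels" is
   read as permuting the assignment map; permuting target trial
   identities is available by flag and is equivalent in distribution for
   this statistic).
6. **Inter-cluster distances** are CCs (or Euclidean distances) between
   cluster-mean vectors; the **agreement** between the two areas'
   distance matrices is the Pearson r over the vectorized off-diagonal
   upper triangles (defined for k ≥ 3).

## What the synthetic generator emulates

`simulateDualAreaSession` draws, per trial, a latent cluster identity
for RFA uniformly over k clusters; CFA's identity equals RFA's with
probability `coupling` and is uniform otherwise. A neuron's
movement-window rate is baseline + a fixed movement gain + its fixed
tuning + its loading on the trial's cluster + noise; events are Poisson
counts with exponential amplitudes on a 30 Hz grid, and fluorescence is
the events convolved with an exponential calcium kernel (decay 1.40 s
RFA / 1.22 s CFA) plus Gaussian noise. Three structural choices matter:

* **Fixed per-neuron tuning** (s.d. 1.0 Hz) makes every trial vector
  share a common pattern, producing the positive baseline trial-to-trial
  CC that the shuffle null exhibits on real data. A per-trial global
  excitability gain would not do this: Pearson CC between trial vectors
  centers across cells and cancels any common offset.
* **Shared latent cluster geometry**: the k cluster archetypes of both
  areas are projections of the same 3-dimensional latent positions.
  Without this, the two areas' inter-cluster distance structures are
  independent by construction and no agreement is possible even at full
  coupling; with it, agreement grows smoothly with coupling, which is
  exactly what the distance-agreement statistic measures.
* **Zero-sum loadings per cluster** keep the field-averaged activity
  comparable across clusters, mirroring the control that cluster
  structure is not a global-excitability artifact.

Defaults are the study-scale conditions: 46 + 24 movement-related
neurons, 65 selected trials, ten latent clusters, 5.4 Hz per-field
acquisition. Under these conditions the pipeline yields 8–13 affinity
propagation clusters per session with the median preference, a coupled
(c = 0.5) intra-cluster CC clearly above its shuffle null, and a
distance-agreement r near 0.5 — the same qualitative regime as the real
data, at a reduced absolute scale because the generator's per-trial
noise is not matched to any particular dataset.

The generator does **not** emulate motion artifacts, neuropil
contamination, slow drift, correlated noise between neighboring ROIs, or
spike-inference errors. Passing recovery tests therefore demonstrates
the correctness and calibration of the statistics, not robustness to
those real-data nuisances.

Behavioral sessions (`simulateBehaviorLog`) plant rule-satisfying and
rule-violating trials (5 mm pull, 400 ms hold, 1 s response window,
2.5–3.5 s inter-cue intervals) with configurable reaction-time
distribution, pre-pull fraction, and lever noise; `detectTrials` must
reproduce the planted labels exactly. The pull onset is defined as the
last sample at or below a noise floor of 3 × the pre-cue baseline s.d.
before the threshold crossing (the onset definition is otherwise open);
success requires the lever to stay continuously beyond the threshold for
the hold duration (continuous hold, not net displacement — the stricter
reading). The pre-pull flag marks excursions above 20% of the pull
threshold between cue and onset (threshold unspecified upstream;
configurable here). Lever noise of 1.78 mm s.d. targets a session lever
correlation of 0.88, via `CC ≈ s / sqrt(s² + σ²)` with s the template
s.d. over the alignment window.

Soma-axon sessions copy each parent spike train to its boutons with
per-event release failures (p = 0.8), 100 ms timing jitter, and
multiplicative amplitude noise (CV 0.6) around the **parent's** event
amplitudes — so the zero-jitter, zero-CV limit reproduces the parent
exactly (CC = 1). At the defaults the parent-bouton filtered CC cluster
sits in roughly [0.63, 0.83] against a background distribution centered
at zero, and matching at the 0.6 CC criterion recovers the planted
parentage exactly.

## Problem sizes and runtime choices

The test suite runs the calibration and power checks on 50 sessions each
at the full study-scale defaults, the distance-agreement monotonicity on
20 sessions per coupling level at a reduced size (24 + 24 neurons, 48
trials, 6 clusters), PSF recovery on 50 beads at SNR 20, and the
classifier type-I calibration on 1000 independent neurons over 40
trials. These sizes were fixed once as a balance between statistical
resolution and desk-scale tractability; the acceptance script re-runs
the same computations at moderately reduced counts and reports every
value with its problem size.

## Known limitations

* The affinity-propagation implementation follows the standard damped
  message-passing updates; like the reference implementation it can
  oscillate on highly degenerate similarity matrices, in which case it
  returns `converged = FALSE` with a warning.
* Real-data absolute levels (intra-cluster CC 0.2+, shuffle null 0.1+)
  are not reproduced numerically by the generator — only the contrasts
  and orderings are; raw recordings would be needed for level-accurate
  emulation.
* HDF5 container input is not provided; long-format CSV (plus JSON
  sidecars) and TIFF cover the interchange needs.
* The eccentricity keep-rule is applied exactly as specified; users whose
  extraction pipeline yields round somata should flip the comparator.
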