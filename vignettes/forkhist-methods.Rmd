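---
title: "Methods: histone-variant organization at replication sites from 3D SMLM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histone-variant organization at replication sites from 3D SMLM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific setting

`forkhist` analyses how histone variants (such as H3.3 and H3.1) are
organized in the nucleus relative to sites of ongoing DNA replication, using
3D single-molecule localization microscopy (STORM) point clouds, and how
their genome-wide enrichment relates to replication timing and
transcription. The package works entirely at the level of *localization
tables* — lists of fitted molecule positions (x, y, z in nm, frame,
channel) — and *coverage tracks* (bedGraph). Raw-movie fitting, microscope
control and read alignment are upstream of this package and out of scope.

Because the raw experimental data of this kind are typically not freely
redistributable, the package ships a first-class synthetic-data module that
generates every input with planted ground truth, so the whole pipeline is
testable offline by parameter recovery.

## Localization preprocessing

* **Drift correction.** Fiducial beads imaged through the whole acquisition
  provide a shared drift trace. The per-frame offset is the mean over beads
  of (position − position at the reference frame), smoothed with a centered
  moving average (default 100 frames; the source data do not dictate a
  window). The offset at the reference frame is 0 by construction. Ends of
  the series use only the available frames; re-extending the window forward
  at the edges would bias the reference value and was deliberately avoided.
* **Channel registration.** Matched bead positions (per-bead time averages)
  give a translation (≥1 bead), rigid+scale (≥2, SVD/Procrustes) or affine
  (≥3) map of channel B onto channel A, with the residual RMS reported.
* **Consecutive-frame merging.** Localizations detected in consecutive
  frames within 50 nm are considered one molecule re-blinking. Linking is
  greedy nearest-first per frame pair; chains collapse transitively to a
  single record at the unweighted mean position, carrying the first frame.
  Whether the mean or the first position should be kept is not dictated by
  the source analysis; the mean is the default and `position = "first"` is
  available. Passes are iterated to a fixed point, which makes the
  operation idempotent — a single greedy pass is not, for adversarial
  configurations.
* **Section clipping** keeps `z_min <= z < z_max` (half-open), matching a
  600 nm optical section.
* **Nucleus segmentation** uses the 2D convex hull of all detections plus
  the observed z range. A convex hull (rather than an alpha-shape) is
  adequate for roughly convex adherent nuclei and keeps the mask convex,
  which the Voronoi clipping exploits.

## Cluster segmentation and density

Histone *conglomerates* and EdU *replication sites* are DBSCAN clusters in
3D Euclidean metric with Eps = 75 nm and MinPts = 10. MinPts counts the
point itself (the common DBSCAN convention; the source analysis does not
state it). Replication foci additionally require ≥ 100 detections; the
threshold is inclusive by default (`strict` switches to `>`), and no size
filter is applied to histone conglomerates, since the detection threshold
is stated for replication foci only. Border points are assigned to the
cluster of their first core neighbor in canonical record order — DBSCAN
border assignment is inherently order-dependent, so the order is fixed
(frame, x, y, z) and the result is permutation-invariant.

Cluster volume is the 3D convex-hull volume (an incremental hull
implemented in the package; no suitable hull library is assumed).
Degenerate (coplanar) clusters are flagged and excluded from density
distributions rather than producing infinities. The normalized density of
a cluster with n detections is `(n / N_nucleus) / V_hull`, with
`N_nucleus` the channel's total detections in the nucleus — so the
statistic is invariant to overall detection efficiency.

Conglomerates *at* replication sites are those whose centroid is strictly
under 200 nm from a site's center of gravity; a hull-containment mode is
provided as the cross-check variant, and the two agree by construction
when conglomerates sit inside site hulls.

## Spatial statistics

* **Recycling score.** Per site: `h / (e * H_total)` where `h` counts
  parental-histone detections inside the site hull, `e` is the site's EdU
  count and `H_total` the nucleus-wide parental count. The score is
  invariant to uniform changes in labeling efficiency.
* **Radial profiles.** Detections are assigned to 50 nm concentric shells
  around a site's center of gravity by 3D distance, and shell counts are
  divided by shell volume. The default volume is the full spherical shell
  (the literal "volume of the corresponding region"); `clip_mode = "slab"`
  intersects each shell analytically with the optical section, because a
  600 nm slab truncates shells beyond ~300 nm. Profiles over a cell's
  sites are pooled by summing counts and volumes per shell before dividing
  (per-site averaging is available via a flag); the pooling order is not
  dictated by the source description.
* **m-function.** The kernel-smoothed density of all A–B pair distances at
  radii 50–500 nm, divided pointwise by the mean of the same statistic
  over 20 paired uniform samples of the same sizes drawn in the nucleus
  mask (seeded). 1 = independence, > 1 attraction, < 1 repulsion. The
  bandwidth (25 nm) and the Monte-Carlo baseline are this package's
  choices; only the normalization and interpretation of the statistic are
  specified by the source analysis. Implementation note: pairs farther
  than `max(radii) + 4 * bandwidth` contribute nothing to the Gaussian
  kernel sums at the evaluated radii, so the pair search is truncated
  there — an exact optimization, not an approximation.
* **Voronoi density.** Each detection owns one polygon of the 2D Voronoi
  tessellation clipped to the convex nucleus mask; cells are built by
  clipping the mask with perpendicular-bisector half-planes of neighbors
  in distance order, stopping at the security radius. Clipped areas
  partition the mask exactly (up to float error), so the area distribution
  is a bias-free local-density readout. Exactly duplicated positions are
  jittered by < 0.1 nm, deterministically, with a warning.
* **Distribution comparisons.** Gaussian KDEs (Silverman's rule, 512-point
  grid over the pooled range) give per-group peaks; the headline effect
  size is the peak shift `100 * (peak_B − peak_A) / peak_A`. Significance
  is a two-sided Mann–Whitney U test with tie correction; stars follow
  `* 0.01 < p ≤ 0.05`, `** 0.001 < p ≤ 0.01`, `*** p ≤ 0.001`, `ns`
  otherwise. A constant sample degenerates to a point mass at its value.
* **Periphery.** A site is peripheral when its centroid is within 500 nm
  (configurable; no reference value exists) of the mask boundary in 2D.

## Genomic landscape

Coverage is averaged per-base over consecutive 10 kb bins, splitting
intervals exactly at bin boundaries, after scaling each track by
`1e6 / (sum of value × width)` — a counts-per-million-equivalent depth
normalization whose scale cancels in the log2 ratio. The log2 sample/input
ratio is defined only where both tracks are positive. Smoothing averages
the nearest 5 *defined* bins centered on the target in genomic order
(chromosome ends use the available bins) — this reading follows the
"smoothed over 5 non-zero bins" phrasing rather than 5 consecutive genomic
bins. Replication timing of a bin is the Repli-seq fraction (S1–S6) with
the highest mean coverage; ties break toward the earlier fraction
(deterministic; ties have measure zero on real data); all-zero bins stay
unassigned. Transcription classes: zero-coverage bins are `none`; among
non-zero bins, type-7 percentiles of log2 coverage give `low` (≤ p10),
`high` (≥ p90) and `mid` otherwise. Both extreme boundaries are inclusive;
the plain-language "lower 10th percentile" is boundary-ambiguous, and the
inclusive rule is asserted in the tests.

## Pulse-chase dilution model

If parental histones were lost only by replicative dilution, the expected
fraction remaining after t hours is `0.5^(t / T)` with T the cell-cycle
length (equivalently `T = ln 2 / growth rate`): 50% loss per cycle.
`retention_summary` compares per-chase-time means against this line and
flags excess loss with a one-sided z-style criterion (mean more than 1.645
standard errors below the expectation), since the experimental readout is
means ± SD against the dashed dilution line.

## The synthetic world

`generate_scene` draws a Thomas process per channel: uniform parent
centers inside an ellipse × z-slab nucleus (default semi-axes 8 × 5 µm —
the source does not state nucleus dimensions; these are plausible HeLa
values — and a 600 nm slab), with Gaussian offspring (σ = 50 nm by
default, ~200 detections per conglomerate, 10% uniform background).
Channel coupling places histone parents relative to EdU parents: a
fraction `1 − 1/c` of A parents sits on B parents for c > 1; candidates
within 300 nm of a B parent are thinned with probability `1 − c` for
c < 1. Molecules blink as geometric chains over consecutive frames
(repeat probability 0.3) with 15 nm localization jitter, and an optional
shared sinusoidal drift. An optional hard-core minimum parent separation
supports the recovery criteria, which are stated for well-separated
clusters. Localization jitter is resampled to keep detections inside the
nucleus region; drift displacement is exempt from that invariant, since
uncorrected drifted data legitimately leave the region.

What the generator does **not** emulate: astigmatic PSF shape and
z-dependent localization precision, camera noise, inhomogeneous chromatin
background, nuclear envelope invaginations, or sequencing-read noise
(genomic tracks are emitted at coverage level). A green recovery test
therefore establishes the correctness of the analysis pipeline on its
stated model, not robustness to every optical artifact of real STORM data.

Genomic tracks plant per-bin timing with a sharp coverage falloff
(factor ~7 between the planted fraction and its neighbors) so the argmax
assignment survives per-track depth normalization, and plant transcription
classes with counts that are exactly consistent with the type-7 percentile
rule, separated by value gaps — which is what makes *exact* recovery a fair
assertion rather than a statistical one. The dilution generator uses
mean-one log-normal noise so group means match the model without bias.

## Numerical choices and degenerate inputs

Hull construction uses a relative tolerance of 1e-10 on the coordinate
range for visibility/degeneracy decisions; containment tests allow a 1e-6
nm slack. Radial shells are half-open `[k·w, (k+1)·w)`. The z-section clip
is half-open. Mann–Whitney p values come from `stats::wilcox.test`
(exact when sample sizes permit and no ties are present, normal
approximation with tie correction otherwise). All generators route their
randomness through an internal seed guard that restores the caller's RNG
state.

## Known limitations

* The Voronoi construction requires a convex mask (true for hull-derived
  masks); non-convex masks would need polygon intersection machinery.
* DBSCAN is exact but in-memory; tables far beyond ~10^6 detections would
  want a compiled neighbor index.
* The m-function baseline assumes uniformity inside the mask is the right
  null; nuclei with strong large-scale density gradients would need an
  inhomogeneous baseline.
* Whole-nucleus extrapolation from a single 600 nm section is reported by
  the upstream study but intentionally not implemented here.
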