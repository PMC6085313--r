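# forkhist

Quantitative analysis of histone-variant organization during DNA
replication from 3D single-molecule localization microscopy (STORM) point
clouds and genomic coverage tracks.

During S phase, nucleosomes ahead of the replication fork are disassembled
and parental histones are recycled onto newly synthesized DNA, while new
histones are deposited alongside. How histone variants such as H3.3 and
H3.1 are arranged around replication sites — and how that arrangement
degrades under replication stress or chaperone depletion — is measurable
from STORM localization tables of a histone channel (SNAP-tag labeled) and
an EdU channel marking newly replicated DNA. `forkhist` implements the full
analysis stack for this question, plus the companion genome-wide analysis
relating histone-variant ChIP enrichment to replication timing (Repli-seq
S1–S6) and nascent transcription.

## What it computes

| Stage | Functions |
|---|---|
| Localization IO and corrections | `read_localizations`, `estimate_drift`, `apply_drift`, `register_channels`, `merge_consecutive`, `clip_z_section`, `segment_nucleus` |
| Cluster segmentation | `dbscan` (Eps 75 nm, MinPts 10), `conglomerate_metrics`, `detect_replication_sites` (≥ 100 detections), `select_near_sites` (< 200 nm) |
| Spatial statistics | `recycling_scores` (h / (e·H_total)), `radial_profile` (50 nm shells), `m_function`, `voronoi_density`, `compare_distributions` (KDE peak shift + Mann–Whitney), `classify_periphery` |
| Genomic landscape | `bin_coverage` (10 kb bins, depth-normalized), `log2_enrichment` (smoothed over 5 defined bins), `assign_timing`, `classify_transcription`, `summarize_by_timing` |
| Pulse-chase | `dilution_model`, `expected_dilution` (0.5^(t/T)), `retention_summary` |
| Synthetic data with ground truth | `generate_scene`, `generate_fiducials`, `generate_tracks`, `generate_dilution_series` |

The core statistics, in the field's notation:

* normalized cluster density: `(n / N_nucleus) / V_hull`, with `V_hull` the
  3D convex-hull volume of the cluster;
* recycling score per replication site: `h / (e · H_total)`;
* radial profile: counts in 50 nm concentric shells around a site's center
  of gravity, divided by shell volume (optionally clipped to the 600 nm
  optical section);
* m-function: KDE of A–B pair distances normalized to the mean over
  seeded uniform re-samplings in the nucleus mask — 1 = independence,
  > 1 attraction, < 1 repulsion;
* peak shift: `100 · (peak_B − peak_A) / peak_A` of Gaussian KDE modes,
  with Mann–Whitney significance stars (`* 0.01 < p ≤ 0.05`,
  `** 0.001 < p ≤ 0.01`, `*** p ≤ 0.001`).

## Worked example

```r
library(forkhist)

## a synthetic S-phase nucleus: 25 EdU site clusters, histone channel
## attracted to them (coupling 2), 10% background, blinking + 15 nm jitter
sp <- scene_spec(n_conglomerates = 25L, detections_per_conglomerate = 180,
                 background_fraction = 0.1, channel_coupling = 2, seed = 11L)
sc   <- generate_scene(sp)
locs <- merge_consecutive(sc$locs)            # collapse re-blinking molecules
hist <- locs[locs$channel == "A", ]
edu  <- locs[locs$channel == "B", ]

congl <- conglomerate_metrics(hist, dbscan(hist, dbscan_params()))
sites <- detect_replication_sites(edu, dbscan_params())
nrow(congl); nrow(sites)
#> [1] 23
#> [1] 24

median(congl$hull_volume_nm3); median(congl$equiv_diameter_nm)
#> [1] 7210000      # nm^3
#> [1] 240          # nm equivalent-sphere diameter

rs <- recycling_scores(hist, sites)
sum(rs$h > 0); mean(rs$score)
#> [1] 10           # sites containing parental signal
#> [1] 5.05e-05     # h / (e * H_total), pooled per condition in practice

rp <- radial_profile_sites(hist, sites, max_radius_nm = 1000)
round(rp$density[1:6] * 1e6, 2)   # detections per 1e-6 nm^-3, 50 nm shells
#> [1] 14.16  8.76  3.17  0.72  0.11  0.07

mf <- m_function(hist, edu, sc$mask, n_baseline = 10L, seed = 2L)
round(c(mean(mf$m), mf$m[1]), 3)
#> [1] 16.633 81.607   # strong attraction at short range, as planted

cmp <- compare_distributions(congl$normalized_density[!congl$degenerate],
                             congl$normalized_density[!congl$degenerate] * 0.7)
round(cmp$peak_shift_percent, 1); cmp$stars
#> [1] -30.1
#> [1] "***"
```

The density histogram shifts by −30% with `***` significance when the
second condition's densities are scaled by 0.7 — the peak-shift convention
used to report density changes through S phase. The radial profile decays
with distance from site centers because the histone channel was generated
attracted to the EdU sites; with `channel_coupling < 1` the same readouts
shift the other way (lower recycling scores, profiles displaced outward),
emulating hydroxyurea treatment or ASF1 depletion.

A command-line wrapper for the generators and basic analyses is in
`inst/cli/forkhist.R` (subcommands `scene`, `tracks`, `dilution`,
`cluster`, `merge`).

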