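---
title: "Homecage behavioral phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homecage behavioral phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homecage8)
```

## The assay and what the package computes

`homecage8` analyzes a 22-hour homecage assay in which eight mice are
imaged simultaneously (1 frame/s, one cage per crop of a 640 x 960
composite).  The assay timeline is a 6 h daytime phase (white screen
background), 6 h of night (red background), 6 h of night during which
three visual stimuli are presented — a rotating moth at elapsed hour 12
and two sets of moving lines at hours 14 and 16 — and a closing 4 h of
daytime.  Summaries are made over 132 ten-minute "periods"; indexing is
1-based, so the first stimulus onset opens period 73 and the onsets are
12 periods apart.  This interpretation makes the stated period ids and
the 2-hour onset spacing mutually consistent, and it is the convention
used throughout the package.

From this assay the package derives a 125-parameter behavioral profile
per mouse, in three blocks:

* **15 tracking-derived parameters** from centroid tracking of the
  segmented mouse blob (movement percentages by assay phase, acclimation,
  habituation to each stimulus, quadrant occupancy);
* **52 pose-derived parameters** from an 8-keypoint pose track (movement,
  scoot, burst and escape speed classes, speeds, acclimation and
  habituation in each measure, hut/peek/window occupancy, wall and food
  distances, sociability at the window);
* **29 syllable usage frequencies and 29 mean bout durations** from a
  discrete behavioral-state sequence (the output of an unsupervised
  syllable classifier; this package consumes the label sequence, it does
  not fit the classifier).

Profiles are z-scored, weighted by the magnitude of their loading on the
first principal component, and clustered with Ward linkage on Euclidean
distances.

## Segmentation and tracking

Frames are segmented in the red channel, where the dark mouse contrasts
with both the white day background and the red night background.  The
threshold is a fixed configurable value (0.5 of full scale) with Otsu's
method available as an automatic fallback; the largest connected
component above a minimum area inside the cage bounds is taken as the
mouse.  Elongation is the major/minor axis ratio estimated from the
blob's second moments, and the head is the blob-boundary point farthest
along the direction of motion (held from the previous frame while the
animal is still).  When the mouse is inside the red hut it is invisible
to the camera; runs of missing centroids of at least 3 frames are
interpreted as hut visits.

Stretch-attend posture (SAP) is not defined quantitatively in the
assay's source literature, so the package uses an operational
definition with both knobs exposed in the configuration: elongation of
at least 2.0 together with centroid displacement of at most 2 px/s.
The frame immediately after a tracking gap has no defined displacement
and is never flagged; on otherwise clean tracks detection is exact.

## Behavior parameters

Speeds are Euclidean displacements between consecutive valid samples
divided by the time gap, in px/s (pixels are the assay's native unit;
no metric calibration is assumed).  Motion classes use increasing
speed cut points still < 2 &le; scoot < 10 &le; move < 40 &le; burst <
80 &le; escape, mirrored by the simulator's state speeds so that class
recovery is exact on noiseless tracks.  These defaults are conventions
carried over from the assay's prior analysis tooling and are
configuration-exposed, not fitted values.

Percentage measures divide qualifying valid seconds by valid seconds in
the interval; frames removed by the likelihood filter (strictly below
0.90) or lost to segmentation are excluded from both numerator and
denominator.  The one deliberate exception is the tracking-derived
`Home` parameter, where time in the hut *is* home-quadrant time even
though the mouse is invisible; the quadrant percentages therefore still
sum to 100.  Empty denominators yield an undefined sentinel (`NA`),
never zero — a mouse that is never visible has unknown movement, not
zero movement.  Undefined entries are imputed by the group mean only at
profile assembly, and flagged.

Acclimation is the value in the last 10-minute bin of hour 1 minus the
value in the first bin — the simplest monotone summary of settling in;
a slope would react to the shape of the decline, which the assay does
not constrain.  Habituation to a stimulus is the absolute level in the
10 minutes following its onset, because group comparisons are made
directly on these levels.  Two open conventions are resolved as
follows, with both variants emitted: wall and food distances are means
over time of the per-frame closest distance (minima attached as
attributes), and the window-partner sociability measure is conditional
on the focal mouse being at the window (the unconditional variant is an
attribute).

## Syllable summaries

A bout is a maximal run of one label.  Usage frequency is the share of
bout *onsets*, not of frames — this keeps frequency and duration
independent, which matters because group effects can lengthen bouts
without changing usage or vice versa (a frame-share variant is attached
for comparison).  The transition matrix is the bout-level chain;
self-transitions are impossible by construction and are excluded.
Rows of syllables that never transition out are flagged rather than
renormalized.

## Gait

Footfall event logs (paw id, contact interval, print geometry and
intensities) are consumed as produced by walkway acquisition software;
print geometry and intensity fields are acquisition-side quantities and
are only aggregated here.  A compliant run crosses the walkway in one
direction in under 10 s; non-compliant runs are excluded, and animals
need 3 compliant runs (configurable) to enter the gait table.

The six normal step sequence patterns follow the standard CatWalk
convention — cruciate (RF-LF-RH-LH, LF-RF-LH-RH), alternate
(RF-RH-LF-LH, LF-RH-RF-LH) and rotary (RF-LF-LH-RH, LF-RF-RH-LH) —
since the assay literature names but does not enumerate them.  The NSSP
score scans four-step sliding windows and accepts any cyclic rotation
of any pattern; it is reported as the share of step windows (the
standard regularity treatment), with a duration-weighted variant
attached because "time spent" is the phrase used in some descriptions
of the measure.  Support classes partition the run window by the set of
paws in contact; their percentages sum to 100 exactly, and run duration
is first-to-last contact start (run-bounds variant attached).  The body
axis needed for paw angles is estimated from the local direction of
travel, as print-only logs carry no spine landmarks.

## Profiles, weights and clustering

Group-level profiles are per-parameter means over a group's mice, and
the principal component analysis operates on the z-scored group-level
matrix by default (a per-mouse mode serves the screening statistics).
Weights are |PC1 loading| normalized to a maximum of 1: the loading's
sign is an arbitrary orientation, so magnitude is the meaningful part;
raw and squared variants are selectable.  The order of operations is
z-score, then weight, then Euclidean distance, then Ward linkage in the
Ward.D2 convention (R dialects differ; D2 operates on the distances
themselves and reduces exactly to classical Ward on squared
increments).  With unit weights the procedure is plain Ward clustering
of z-scored profiles, which is asserted in the test suite.

## The statistical screening layer

Normality is recorded per group with the Shapiro-Wilk test; the
screening tests themselves are nonparametric.  The per-parameter screen
is the unpaired two-sided Wilcoxon rank-sum test (exact null for small
tie-free samples, normal approximation with tie correction otherwise),
run per age timepoint for untreated AD versus WT, with the direction of
effect reported as the median difference.  No multiple-testing
correction is applied by default — each parameter is screened at raw
p < 0.05, matching how such screens are conventionally reported — and a
Benjamini-Hochberg option exists for stricter use.  Syllable statistics
use Kruskal-Wallis with Dunn's two-sided z-tests on mean ranks
(tie-corrected; no dedicated Dunn implementation is available in the
installed package set, so the z-tests are computed directly from the
standard mean-rank formula and verified against hand enumeration).
Gait parameters use two-way ANOVA (genotype x age) with Tukey's HSD run
only when the interaction is significant.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be
validated against planted ground truth.  One simulated mouse is a
five-state switching random walk (still/scoot/move/burst/escape) whose
bout lengths are geometric with a 6 s mean and whose state speeds sit
mid-bin, overlaid with three renewal processes: hut visits (exponential
bouts, 240 s mean, planted occupancy 0.30), window visits (30 s mean,
occupancy 0.10) and stretch-attend bouts during rest (share declining
over hour 1).  Activity probability follows the schedule: 0.35 by day,
0.62 by night, 0.60 declining through hour 1 (acclimation), 0.70 in the
first hour of night, and stimulus-specific levels in the three
post-onset windows.  Keypoints are laid out along the body axis with
0.5 px placement noise, and a configured fraction (10%) of likelihoods
is drawn below the 0.90 filter threshold.  Partner sociability is
planted by correlating the partner's window-visit bouts with the focal
mouse's at a set co-occurrence rate (0.50), with the free walk kept
clear of the window corner so that near-window time comes from the
deliberate visit layer and the rate is recoverable by counting.

The genotype, age and treatment effect structure perturbs exactly the
behavior families in which the real assay reported group differences:
first-hour and first-night-hour activity, the fast-locomotion share,
the acclimation and SAP-decline slopes, responses to the moth and first
moving-lines stimuli, hut occupancy, wall distance, window-partner
co-occurrence, and a syllable-repertoire concentration with lengthened
stretch/tail-groom bouts.  Ageing lowers activity and raises hut
occupancy in both genotypes; treatments pull the AD offsets back toward
zero by fixed fractions (cyclosporine 0.85, nebivolol 0.60,
cabozantinib 0.45).  These values are design constants of the
generator, chosen once to emulate the described effect directions at
magnitudes detectable at n = 8 per group; they are not fitted to
reproduce any published statistic.

What the generator does **not** emulate: real pose-estimation error
structure (correlated jitter, identity swaps, occlusion), the empirical
covariance between behavior parameters of real mice, circadian drift
within phases, and any camera artifact.  Consequently, passing
recovery tests demonstrates that the *pipeline* computes what it claims
on data with known truth — not that the synthetic cohort is
statistically exchangeable with real animals.  In particular, screening
counts and PCA variance shares measured on synthetic cohorts differ
from values measured on real animals, and the published per-mouse
raw-data table is not redistributable here, so the acceptance suite's
supplementary-reproduction block runs on a clearly-labelled synthetic
stand-in and is expected to deviate from the printed values.

## Problem sizes and numerical choices

The test suite runs most simulations at 1/6 to 1/600 of the 22-hour
assay (the generators scale every phase, onset and bout length
proportionally), with full-scale runs reserved for the quantities that
need long averages: planted-occupancy recovery (±2 percentage points at
79,200 frames), the 3 s mean syllable bout length (±0.2 s), and the
window-partner rate (±3 points).  The acceptance script simulates the
full-scale designs: 6 screening groups and 10 study groups at 8 mice
per group.  Monte-Carlo tolerances quoted in tests are set from the
binomial/renewal sampling error at those sizes.  Ties in quadrant
assignment (boundary pixels) resolve to the nearest quadrant centroid
so that the quadrants always partition the cage; transition rows with
no outgoing bouts are flagged rather than renormalized; PCA drops
zero-variance parameters with a warning and assigns them zero weight.

## Known limitations

* Head estimation from blob geometry needs motion to orient itself; for
  a mouse that never moves, the head-end choice is arbitrary.
* The image-tracking stage assumes one mouse per cage and no occluders
  other than the hut.
* `Peek` requires the nose keypoint to survive the likelihood filter;
  heavy nose occlusion deflates it.
* Dunn and screen p-values are raw by default; at 52 parameters and 3
  timepoints, family-wise false positives are expected and intended to
  match the conventional reporting of such screens.
* The six-pattern NSSP set and the motion-class cut points are
  conventions, not fitted constants; both are configuration-exposed.
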