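# homecage8

Behavioral phenotyping for a 22-hour, 8-cage homecage imaging assay in
mice, built for longitudinal comparisons of Alzheimer's-disease model
mice (3xTg-AD) against wild-type controls and drug-treated cohorts.

Classic behavioral tests (open field, elevated plus maze, Y-maze) expose
animals briefly to unfamiliar chambers and suffer from notorious
inter-study variability. The assay this package analyzes takes the
opposite approach: each mouse spends 22 hours in its own cage while a
timelapse camera (1 frame/s) records it through a scripted day/night
cycle with three visual stimuli presented during the night (a rotating
moth and two sets of moving lines, 2 h apart). From these recordings the
package computes a **125-parameter behavioral profile** per mouse:

| Block | Count | Source |
|---|---|---|
| Tracking-derived (movement, acclimation, habituation, quadrant occupancy) | 15 | centroid tracking of the segmented mouse blob |
| Pose-derived (speed classes, sociability, hut/peek/window occupancy, distances) | 52 | 8-keypoint pose tables (DeepLabCut CSV dialect) |
| Syllable usage frequencies + mean bout durations | 29 + 29 | discrete behavioral-state label sequences |

Profiles are z-scored, weighted by the magnitude of each parameter's
loading on the first principal component (w_i = \|l_i\| / max_j \|l_j\|),
and clustered with Ward linkage (Ward.D2) on Euclidean distances, so
that treated groups can be placed relative to untreated and wild-type
clusters. A CatWalk-style gait module computes step-sequence regularity
(% of four-step windows matching one of the six normal step sequence
patterns), support percentages, base of support, cadence and per-paw
timing from footfall event logs, with the assay's run-compliance rule
(one-directional crossing in < 10 s). A statistics layer provides the
screening tests used with such assays: Shapiro-Wilk normality gate,
per-parameter two-sided Wilcoxon rank-sum screens per age timepoint,
Kruskal-Wallis + Dunn for syllable statistics, and two-way ANOVA with
conditional Tukey HSD for gait.

Every input the pipeline consumes can also be *simulated* with planted,
recoverable group effects (`simulate_pose_track()`,
`simulate_syllables()`, `simulate_footfalls()`, `simulate_cohort()`),
which is how the package validates itself end to end.

## Worked example

```r
library(homecage8)
schedule <- make_schedule()            # the canonical 22-h assay
geometry <- cage_geometry()            # one cage, 240 x 320 px

mouse   <- group_spec("AD", "old")     # an old 3xTg-AD mouse
pose    <- simulate_pose_track(mouse, schedule, geometry, seed = 42)
partner <- simulate_pose_track(group_spec("WT", "old"), schedule, geometry, seed = 43)
partner <- correlate_window_visits(partner, pose, geometry, cooc = 0.5, seed = 44)
track   <- truth_track(pose, geometry)

params <- compute_param_vector(track, filter_pose(pose), filter_pose(partner),
                               geometry, schedule)
round(params[c("fiji_M1", "fiji_M7", "fiji_Home", "dlc_Sc1", "dlc_B7",
               "dlc_Wall", "dlc_Window Partner")], 2)
#>            fiji_M1            fiji_M7          fiji_Home            dlc_Sc1
#>              36.21              56.31              52.79              11.13
#>             dlc_B7           dlc_Wall dlc_Window Partner
#>               1.38              66.00              55.78
```

`fiji_M1` is the percentage of visible seconds the mouse moved during
its first hour in the cage (36% — reduced by the planted AD effect),
`fiji_M7` the same for the first hour of nighttime, `fiji_Home` the
share of time in the home quadrant (hut time included), `dlc_Sc1` the
share of first-hour seconds in the slow "scoot" speed class, `dlc_B7`
the burst share in the first night hour, `dlc_Wall` the mean distance
(px) to the nearest cage wall, and `dlc_Window Partner` the share of
this mouse's window visits during which the partner mouse was also at
its window (planted co-occurrence 0.5).

```r
syl <- simulate_syllables(schedule = schedule, seed = 42)
syllable_summary(syl)
#> syllable_summary: 26490 bouts, 29 of 29 syllables expressed

run <- simulate_footfalls("Aa", n_steps = 16, seed = 42)
validate_run(run); step_sequence_nssp(run); run_stats(run)[["cadence"]]
#> compliant: TRUE  NSSP: 100 %  cadence: 8.53 steps/s
```

The whole pipeline — cohort simulation, Wilcoxon screens, profile
assembly, PCA weights, weighted Ward clustering — runs from one call:

```r
res <- run_pipeline(run_config(seed = 7, n_per_group = 8, scale = 1/6))
res$screens$dlc                 # screening summary, untreated AD vs WT
sum(res$pca$explained[1:2])     # variance captured by PC1 + PC2
res$report$members              # cluster membership at k = 3
```

Artifacts (cohort table, screen CSV, profile CSV, Newick dendrogram,
PC1 weights, run log with every threshold and seed) are written under
`out_dir`.

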