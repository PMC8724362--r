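# sonocordance

Pixel-wise concordance analysis of automated and expert heart border
tracings on B-mode ultrasound images.

## The problem

Automated ultrasound devices (bladder scanners) locate a fluid-filled
structure and trace its border without any operator interpretation. During
cardiac arrest the motionless, blood-filled heart looks to such a device
much like a bladder, which raises a practical question for resuscitation
care: **how closely do the device's automatic heart border tracings agree
with tracings made by experts in focused cardiac ultrasound, and how does
that agreement change across physiologic states** — the beating heart before
arrest, fresh arrest with crisp borders, and late arrest where echogenic
clot forms inside the chambers and confuses automated border finding?

`sonocordance` implements the full analysis workflow of such a study:

1. **Tracing to mask** — a tracing overlay (a coloured closed curve on the
   image) is extracted by colour, morphologically closed to bridge
   rasterization gaps, filled by flood fill from the raster border, and
   cropped to the fan-shaped sector scan area, giving a binary mask
   (white = pixel within tracing).
2. **Pixel-wise comparison** — a reviewer mask (reference) and the device
   mask (test) decompose every sector pixel into true positive, true
   negative, false positive, false negative; agreement is summarised by the
   Sørensen–Dice index

   SDI = 2·TP / (2·TP + FP + FN) = 2|A∩B| / (|A| + |B|),

   1 for perfect agreement, 0 for none, and visualised as a four-colour
   rendering (TP yellow, TN white, FP red, FN green).
3. **Blinded study workflow** — eligibility narrowing to intercostal spaces
   where the LV/LVOT is visualized, randomized screening to a per-state
   quota with rib-shadow exclusion, blinding and shuffling (device tracings
   are digitally obscured so reviewers free-trace), scoring, and the
   per-reviewer × per-state mean (SD) summary table.
4. **Synthetic data** — a seeded phantom generator simulates biplane scan
   sets (12 images = 6 orthogonal pairs per scan) of a porcine heart across
   the three states, including per-cycle chamber motion, echogenic clot,
   speckle, rib-shadow acquisition failures, a configurable device tracer
   with state-dependent error (clot undertracing in late arrest), and
   multiple expert reviewers — so the whole pipeline runs and is tested
   without any proprietary scanner data.

## Worked example

```r
library(sonocordance)

cfg   <- phantom_config(128, 96)                 # compact phantom raster
ss    <- generate_scan_set(cfg, "a01", 5, "arrest")
img   <- ss$images[[1]]; truth <- ss$truth_masks[[1]]

dev <- fill_tracing(simulate_device_tracing(img, truth, cfg), dim(truth))
rev <- fill_tracing(simulate_reviewer_tracing(img, truth, "r1", cfg), dim(truth))

(ca <- confusion_areas(rev, dev))
#> confusion_areas: TP 837, TN 4730, FP 24, FN 43 (total 5634)
area_percentages(ca)
#>     tp     tn     fp     fn
#> 14.856 83.955  0.426  0.763
sdi(ca)
#> [1] 0.9615164
```

837 of the 5634 sector pixels are traced by both the reviewer and the
device, 24 by the device only (red in `render_agreement()`), 43 by the
reviewer only (green); the Dice index of 0.962 reflects the near-perfect
agreement expected at arrest, when borders are crisp and motionless.

A full simulated study (two animals, quota 20 images per state, three
reviewers):

```r
rc  <- run_config(phantom = cfg, quota_per_state = 20L, n_animals = 2L,
                  master_seed = 1L)
res <- run_study(rc)
res$summary
#> Sorensen-Dice index by reviewer and physiologic state
#>  reviewer    pre_arrest        arrest   late_arrest
#>        r1 0.900 (0.017) 0.962 (0.005) 0.606 (0.046)
#>        r2 0.900 (0.015) 0.958 (0.007) 0.600 (0.048)
#>        r3 0.893 (0.020) 0.952 (0.007) 0.599 (0.044)
#>    pooled 0.898 (0.018) 0.957 (0.008) 0.601 (0.045)
```

Each cell is the mean (sample SD) Dice index over that reviewer's images in
that state; the pooled row averages the three reviewer means. The simulator
reproduces the qualitative signature of the real study: agreement is
highest at arrest, slightly lower pre-arrest (cardiac-cycle motion), and
collapses in late arrest, where the device undertraces echogenic clot that
human reviewers include within the heart border.

A thin command-line wrapper over the same functions lives at
`inst/cli/sonocordance.R` (`simulate`, `screen`, `blind`, `score`,
`report`; global `--seed`, `--config`, `--outdir`, plus `--version` /
`--help`).

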