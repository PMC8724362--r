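---
title: "Methods: simulated concordance analysis of automated heart border tracings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated concordance analysis of automated heart border tracings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonocordance)
```

## Scope and model

`sonocordance` quantifies the agreement between an automated ultrasound
device's heart border tracings and expert reviewer tracings, pixel by
pixel. The unit of analysis is a pair of binary masks on the same B-mode
raster: the reviewer mask is treated as the reference (known truth), the
device mask as the test. Every pixel of the fan-shaped sector scan area is
classified as TP (in both masks), FN (reviewer only), FP (device only) or
TN (neither), and agreement is summarised by the Sørensen–Dice index
$\mathrm{SDI} = 2TP/(2TP+FP+FN) = 2|A\cap B|/(|A|+|B|)$. The index is
symmetric in the two masks; the reference/test orientation matters only for
the FP/FN labels and the red/green colours of the agreement rendering.

The statistical output is descriptive: per (reviewer, state) cells of mean
and sample standard deviation ($n-1$ denominator) of the per-image SDI, and
a pooled row per state formed as the unweighted arithmetic mean of the
reviewer means (with its SD taken over all image × reviewer pairs). No
between-state inference is computed. Which dispersion the source table
intended is not deducible from the table itself; the sample SD is the
conventional choice for summary tables and is the one we document and test.

## From tracing to mask

Tracings enter the pipeline as overlays: sets of curve pixels, either
simulated directly or recovered from an annotated RGB image by colour
matching (device pure blue `(0,0,255)`, reviewers magenta `(255,0,255)`,
per-channel tolerance 0 for synthetic renderings, ~30 for compressed real
images). `fill_tracing()` converts an overlay to a mask:

1. morphological closing with a disc of radius `closing_radius` (default
   2 px) bridges rasterization gaps of 1–2 px, which hand- and
   machine-drawn curves routinely contain;
2. the exterior is identified by 4-connected flood fill from all raster
   border pixels — an 8-connected curve is a barrier to 4-connected
   background, the standard digital-topology pairing;
3. the mask is the complement of the exterior: interior plus curve, so
   boundary pixels count as inside (this choice is symmetric across raters
   and maximises agreement between two tracings of the same border);
4. gap-sealing pixels introduced by the closing that are 4-adjacent to the
   exterior are *not* counted as traced area. Without this rule the closing
   slightly thickens thin curves at staircase notches and a noiseless
   round-trip (mask → boundary → fill) would not reproduce the mask; with
   it, filling the 4-boundary of any simply-connected region recovers the
   region exactly, a property the test suite exercises on randomized blobs;
5. the result is cropped to the sector scan area.

A curve that encloses nothing after closing raises an "open contour" error
reporting the radius used; a self-intersecting curve that encloses several
regions keeps the largest with a warning. Both-empty mask pairs make the
SDI undefined and are an error rather than a conventional 0 or 1: an empty
pair always indicates an upstream fill failure, and a silent convention
value would contaminate state means.

Percentages of the confusion areas are reported over the sector area, not
the full rectangle, because out-of-sector pixels carry no echo signal;
`confusion_areas()` accepts an explicit `sector` argument (e.g. an all-true
matrix) where the rectangular convention is wanted. Printed percentages are
rounded half-away-from-zero to 3 decimals, so the four values sum to
100.000 within 0.002.

## Sector geometry

The scan area is a circular sector with apex at the top-centre of the
raster and a 120° aperture, the fan shape of sector transducers. Its radius
is the largest for which the fan is fully inscribed,
$\min(h-1, (w-1)/2\sin 60^\circ)$, which keeps the analytic area
$\theta r^2/2$ applicable (the pixelised area matches it within 1% at the
raster sizes used). Pixels outside the sector hold a reserved background
value (0) and are excluded from every count.

## The phantom generator

The generator stands in for data that cannot be shipped: porcine B-mode
images and a proprietary tracing AI. It emulates the acquisition and error
structure the analysis assumes, not ultrasound physics.

* **Acquisition.** Each scan produces 12 images (6 orthogonal biplane
  pairs); scans cover intercostal spaces 4–8 per animal and state. A scan
  raster defaults to 1616 × 1216 (≈1.97 M pixels, the full device
  resolution); all packaged tests and the acceptance script run at 128 × 96
  (and 64 × 48 for manifest-only arithmetic), sizes chosen so the complete
  suite exercises hundreds of fills in a couple of minutes while keeping
  ≥ 800 chamber pixels per image.
* **Appearance.** Dark chamber (mean intensity 40) on a bright speckled
  background (mean 160, multiplicative Gaussian noise, default sd 25 at the
  background mean), echogenic clot blobs at 150, rib shadow as a vertical
  band (15% of image width, intensity 20) over the heart. Intensities are
  plausibility choices; the analysis only requires that clot be separable
  from chamber by a fixed threshold (100).
* **States.** Pre-arrest scales the chamber semiaxes per image by
  $1 + a\sin\phi_k$ with phases spread over the 12 images
  (`cycle_amplitude` $a$, default 0.12 — a realistic fractional
  end-diastole/end-systole dimension change); arrest is motionless with
  crisp borders; late arrest adds `clot_count` (4) blobs adjacent to the
  border covering `clot_fraction` (0.50) of the chamber area, the regime
  that drives device agreement toward the observed ≈0.6.
* **Tracers.** Device and reviewer tracings are the truth boundary
  perturbed by smooth radial noise: 24 i.i.d. Normal(0, sd) knots joined by
  a periodic spline. Device sd is per state — 0.14, 0.04 and 0.08 of the
  minor semiaxis for pre-arrest, arrest and late arrest — encoding that
  motion blurs borders pre-arrest and that arrest borders are crisp; in
  late arrest the device additionally *undertraces*: echogenic pixels
  inside the chamber are excluded from its traced region (largest connected
  component kept), while reviewers trace the full outline. Three default
  reviewers use 0.04/0.05/0.06 of the minor semiaxis. With zero jitter and
  no clot, the filled tracing equals the truth mask exactly, which anchors
  the whole tracing → fill → score path.
* **Reproducibility.** Every stochastic draw comes from a substream seeded
  by an FNV-1a hash of (master seed, animal, ICS, state, scan, plane,
  role), so outputs are pure functions of (config, identifiers, seed) and
  independent of generation order; manifests can be produced without
  rendering pixels and still carry the same rib-shadow flags.

What the phantom does **not** model: point-spread-function blur,
attenuation, anisotropic speckle, out-of-plane anatomy, reviewer bias that
correlates across images, or residual visibility of obscured tracings
(obscuring here is exact median infill and is verified to leave no
extractable pixel). Passing tests therefore demonstrate correctness of the
measurement pipeline and qualitative fidelity of the state ordering — not
quantitative agreement values transferable to real scanner data.

## Study workflow choices

* Screening draws images without replacement in one seeded shuffled order,
  stratified by state: a drawn image whose state quota is already met is
  skipped unscreened; flagged (rib-shadow) images are screened, excluded
  and recorded; the draw stops when every state reaches quota. Uniform
  drawing without replacement is assumed for "randomly selected";
  stratification is what guarantees an exact per-state quota.
* Blinding assigns zero-padded sequential codes *after* a seeded
  Fisher–Yates shuffle, so code order carries no acquisition information;
  reviewer-facing artifacts (packet CSV, coded file names) contain no
  state, animal or ICS substrings, and the test suite string-scans them.
* The packaged screening fixture (`example_screening_manifest()`) encodes a
  study screening log — 828 eligible images of which 10, placed among the
  first 150 screened under the fixture seed, carry rib shadows — so that
  screening it at quota 50/state reproduces 160 screened / 10 excluded /
  150 retained deterministically.
* In synthetic mode exclusion is decided by the manifest's
  `rib_shadow_flag`; for real images the same column can be filled from a
  human decision list before screening.

## Numerical and degenerate-input conventions

Closing radius 2 px default (configurable); 4-connectivity for background
and component labelling throughout; half-away-from-zero rounding for
printed percentages; empty overlays, empty truth masks, unknown reviewer
ids, unlabelled (animal, ICS) pairs, exhausted screening pools, missing
masks and both-empty mask pairs all raise errors naming the offending
field, image code or state rather than degrading silently.

## Problem sizes

The packaged checks run the simulator at 128 × 96 with quota 20/state and
two animals (ordering recovery, 20 seeds), quota 10/state (jitter
parameter recovery, 10 seeds), and quota 4–5 for end-to-end smoke and
byte-identity runs; oracle comparisons use 32 × 32 mask pairs and 64 × 96
contour rasters. These sizes were chosen as the smallest at which chamber
masks remain several hundred pixels — large enough that per-image Dice is
dominated by the modelled error structure rather than quantization — and
are stated here as the package's documented reference conditions.

## Known limitations

* The simulator's state ordering (arrest > pre-arrest > late arrest in
  mean SDI) is by construction — per-state jitter and clot undertracing —
  and encodes a modelling interpretation of *why* pre-arrest agreement is
  lower (cycle motion); it is a design choice, not a measured fact.
* Absolute simulated SDI values depend on raster scale (boundary error
  scales with perimeter/area) and are not calibrated to the real study's
  printed means; only counts, the worked percentage example, and
  qualitative structure are reproduced quantitatively.
* Tracings are star-shaped around the chamber centroid by construction;
  genuinely non-star-shaped reviewer tracings (e.g. figure-eight slips of
  the stylus) only enter through the self-intersection handling of
  `fill_tracing()`.
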