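---
title: "Quantifying wound redox state from NADH/FAD autofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wound redox state from NADH/FAD autofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

NADH and FAD are the two autofluorescent coenzymes of mitochondrial energy
metabolism: NADH reports the reduced pool, FAD the oxidized pool. Their
fluorescence intensity ratio

$$RR = \frac{I_{NADH}}{I_{FAD}}$$

is a label-free marker of the mitochondrial redox state — lower values mean
a more oxidized tissue, which in skin wounds is associated with oxidative
stress and impaired healing. Diabetic (db/db) mouse wounds become markedly
more oxidized than non-diabetic controls over the first week after
wounding, while failing to close; this package implements the image
processing and statistics needed to quantify that difference from
multi-channel fluorescence images, and a synthetic-cohort generator that
plants those effects with known ground truth so the whole chain is testable.

Three markers are computed per animal:

* **Surface RR** — the mean pixelwise NADH/FAD ratio over the wound region
  of an in vivo 2D image: $\mathrm{SurfaceRR} = \frac{1}{N}\sum_n r_n$ over
  wound pixels.
* **Normalized wound area** — the wound pixel count at day $t$ over the
  day-0 count, $N(t)/N(0)$. The pixel size is constant across days, so the
  physical-area ratio reduces to a count ratio: 1 at wounding, decreasing
  with closure.
* **Volumetric RR** — the mean voxelwise ratio over the wound voxels of a
  3D cryo-imaged biopsy, $\mathrm{VolumetricRR} = \frac{1}{N_v}\sum_n r_n$.

## Calibration model

**Cuvette normalization (in vivo).** Excitation-lamp output drifts from day
to day, which would confound any longitudinal intensity comparison. Each
imaging session therefore includes a reference frame per fluorescence
channel: a cuvette of a standard fluorophore solution. Tissue frames are
divided by the mean intensity of the same-day, same-channel cuvette frame.
Because the lamp factor multiplies tissue and cuvette alike, the calibrated
frame is exactly drift-free: $(c\,I)/(c\,M) = I/M$. The cuvette mean is
taken over all pixels of the cuvette frame — the reference is nominally
uniform, and a full-frame mean is the least arbitrary region choice.
Calibrated frames carry a flag; calibrating twice is treated as a contract
violation rather than silently squaring the correction.

**Flat-field correction and background zeroing (cryo).** Cryo-imaging
illumination is spatially non-uniform. Every slice is divided by the
channel's flat-field frame normalized to its own mean
(`flat / mean(flat)`), which removes the spatial pattern while preserving
the global intensity scale (the stack mean is unchanged to numerical
precision). Low-intensity background voxels — frozen embedding medium and
empty space — are then set to zero and excluded from all redox statistics.
The cutoff is a fraction (default 0.10) of the stack's 99.5th-percentile
intensity; anchoring to a high percentile rather than the maximum keeps
isolated hot voxels from inflating the cutoff. Correction is applied before
zeroing (the threshold is then measured on illumination-corrected
intensities); the order is configurable.

**Saturation.** Pixels at the 14-bit full scale (16383) are retained but a
session whose frames are more than 1% saturated triggers a warning.

## Segmentation

The wound region is delineated on the white-light channel, where the wound
bed reflects much less light than the surrounding shaved skin. The
automated procedure standardizes what is otherwise a manual visual step:
median-smooth (3×3), Otsu threshold, keep the darker class, retain the
largest 8-connected component (ties broken by the centroid closest to the
frame centre, since wounds are centred by protocol), fill holes, and apply
one binary opening of radius 1. A contrast-free frame raises an error
directing the user to the manual-mask path: hand-drawn masks (PNG/TIFF,
nonzero = wound) are first-class inputs for real data, shape-checked
against their frame. Cryo biopsies are whole-wound excisions, so the
volumetric wound mask is simply every voxel that survives background
zeroing in both channels.

## Ratio maps and numerical choices

The ratio is computed pixel-by-pixel inside the mask. A raw division is
unbounded where FAD approaches zero, so pixels with calibrated FAD below a
floor — default 1% of the median calibrated FAD inside the mask — are
marked undefined rather than contributing arbitrarily large ratios; the
excluded fraction is reported. The Surface/Volumetric RR divisor is the
number of *defined* ratios (`n_valid`), not the mask count `N`: an
undefined ratio cannot be counted as zero without biasing the mean
downward. Both counts are reported so either convention can be reproduced.
Histograms use 100 bins over ratio range [0, 4] by default, with explicit
underflow/overflow bins so bin fractions always sum to one; the mean of a
finely binned histogram agrees with the Surface RR to well under 0.5%.

Wound pixel counting is literal: a disk of radius $r$ pixels contains the
lattice points within Euclidean distance $r$ of the centre. At the
full-scale geometry (5 mm radius at 40 µm/pixel, i.e. $r = 125$ px) this
count is 49,077 — close to, but deliberately not identical with, the
continuous-area approximation $\lfloor\pi r^2\rfloor = 49{,}087$; the test
suite pins the exhaustive count.

## The synthetic cohort

The generator emulates the study design end to end: 6 animals per group
imaged in vivo at days 0, 2, 4 and 6 after a 10 mm circular full-thickness
wound, plus biopsy cohorts of 4/group at day 0 and 6/group at day 6 for
cryo-imaging. Its defaults *are* the study conditions:

| setting | default | rationale |
|---|---|---|
| surface RR trajectory, control | 1.2 at all days | controls hold a steady redox state |
| surface RR trajectory, diabetic | 1.2, 0.80, 0.60, 0.468 | divergence from day 2; a 61% drop by day 6 |
| volumetric RR, day 6 | 1.2 vs 0.408 | a 66% control–diabetic difference |
| control radius schedule | 5.0, 4.0, 3.0, 2.2 mm | visible monotone closure |
| diabetic radius schedule | constant 5.0 mm | no closure |
| animal random effect | SD 0.03 | between-animal repeatability |
| lamp drift | lognormal σ = 0.15 /day/channel | day-to-day excitation variation |
| camera noise | Poisson (gain 4) + Gaussian (10 DN), 14-bit | the standard CCD model |
| cuvette frames | uniform 1000 DN per channel | nominal reference level |

Frames default to 256×256 pixels with the geometry scaled to half (the
wound radius becomes 62.5 px); a 512×512 frame holds the full-scale 125 px
wound. The scale is recorded in the ground-truth sidecar. Each subject-day
truth value is `group-day mean + animal effect + b·(A − A_sched) + ε`,
where the area-coupling term ties an animal's redox state to how far its
wound area deviates from its group-day schedule, with slope `b = −0.5`
(the least-squares slope of the planted group trajectories on scheduled
area — larger wounds, more oxidized). The noise SD comes from the closed
form `σ² = b²·Var(A)·(1 − R²)/R²` with a target determination of 0.72 and
`Var(A)` taken over the planted area schedules (σ ≈ 0.097).

Centring the coupling on each group-day schedule preserves the planted
group trajectories exactly — the alternative, centring on the pooled area
mean, would shift every diabetic cell by a constant and destroy the planted
61% decline. The price of that choice is visible in the pooled
area–redox regression: because diabetic truth areas are pinned at exactly 1
while diabetic RR spans 1.2→0.468, the pooled scatter is L-shaped and its
attainable $R^2$ is capped near 0.29 regardless of noise level (the
replicate experiment in the test suite measures ≈ 0.29). Real cohorts
reach higher determinations through between-animal area variability that
the generator's fixed schedules intentionally exclude, and the
corresponding acceptance expectation is left failing with this analysis
rather than loosened. The regression's negative slope — the recoverable
part — is reproduced on every default cohort.

What the generator does **not** emulate: keratin autofluorescence bleeding
into the FAD channel, fur/hair artifacts, optical point-spread or spectral
bleed-through, wound-edge substructure (epithelial tongue, granulation
tissue), or inter-day registration error. Passing tests therefore certify
the processing chain, not robustness to those real-data confounds.

## Statistics

The longitudinal layer mirrors common practice for two-group repeated
designs: a split-plot (two-factor repeated-measures) ANOVA with group as
the between-subject factor and day as the within-subject factor, computed
from explicit sums of squares — group, subject-within-group, day,
group×day, and day×subject-within-group — so every term is checkable
against a brute-force decomposition (the suite also cross-checks against
`aov()` with an `Error(subject/day)` stratum). Greenhouse–Geisser epsilon
is estimated from the pooled within-group covariance and reported, with the
uncorrected p-values as the headline and GG-adjusted ones alongside. Tukey
HSD contrasts compare groups at each day, using the studentized-range
statistic with the pooled within-group variance at that day
(Tukey–Kramer form for unequal sizes). Pearson correlations and the
least-squares line come from the explicit product-moment sums, with the
two-sided p from the t transform. Group-day cells are summarized as
mean ± SE (SD/√n). The three markers are tested without cross-marker
multiplicity adjustment; this is noted in the output metadata.

A calibration experiment in the test suite runs 200 replicate cohorts:
with the planted trajectories the group×day interaction rejects in ≥ 90%
of cohorts, and with the group trajectories equalized the rejection rate
stays at the nominal 5% level (compound-symmetric noise makes the
uncorrected F exact there).

## Problem sizes and runtimes

The unit tests run on 96×96 frames and 32×32×16 stacks (2 animals/group),
where a full session renders in milliseconds. The end-to-end recovery
experiments use the default 256×256 cohort — 48 in vivo sessions and 20
biopsies — which simulates and analyzes in about half a minute; the
replicate regression experiment uses 50 cohorts at 96×96. These sizes were
chosen so the full suite exercises every path at comfortably interactive
speed while keeping the planted geometry (wound-to-frame ratio, closure
schedule) identical to the full-scale setup.

## Limitations

* The redox ratio is a whole-wound summary; regional substructure is
  deliberately out of scope.
* The synthetic cohort cannot validate robustness to keratin interference
  or registration drift (see above).
* ANOVA assumes a balanced design — every subject observed at every day;
  unbalanced tables are rejected with an explicit list of missing cells
  rather than silently dropped.
* Saved ratio maps use a fixed file scale (ratio/8 in 32-bit float TIFF,
  undefined pixels as 0 plus a companion validity mask), because float
  TIFF storage here is defined only on [0, 1].
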