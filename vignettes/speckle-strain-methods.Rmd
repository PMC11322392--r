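---
title: "Quantifying dorsal neck-muscle deformation by ultrasound speckle tracking"
author: "SpeckleStrain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dorsal neck-muscle deformation by ultrasound speckle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpeckleStrain)
```

## The measurement problem

B-mode ultrasound of the dorsal neck shows five stacked muscle layers in a
longitudinal view at the C4 level: trapezius (TR) on top, then splenius
(SP), semispinalis capitis (Scap), semispinalis cervicis (Scerv) and
multifidus (MF). The sub-resolution micro-structure of each muscle scatters
the beam into a characteristic interference pattern -- *speckle* -- that
moves and deforms with the tissue. Following a small region of that pattern
frame by frame therefore measures local muscle motion without any external
marker.

`SpeckleStrain` quantifies this motion for a paced head-rotation task: a
participant rotates the head 20 degrees and back, in time with a metronome,
while a contact switch marks the start (midline), the 20-degree reach and
the stop of every rotation in the recording's sync channel. A 15 mm region
of interest (ROI) is placed along the fiber direction of each muscle in the
first frame and tracked through the video; the analysis then concentrates
on one rotation cycle (the tenth, by convention of the protocol emulated
here).

Because clinical recordings of this kind are not freely redistributable,
the package ships a synthetic-cohort module that renders speckle videos
with *exact, known* layer strain. Every downstream stage -- tracking,
curves, areas, inference -- is validated against that ground truth.

## The deformation model

### ROI tracking with a linear strain fit

Each ROI carries `nPoints` (default 15) evenly spaced measuring points.
Between consecutive frames, each point is tracked by pyramidal
Lucas-Kanade registration: the displacement `d` minimizing the local sum
of squared intensity differences over a `(2w+1)^2` window (default
half-size `w = 8` px, 3 pyramid levels, at most 30 iterations, convergence
at 0.01 px). Points on texture-free patches (Shi-Tomasi minimum eigenvalue
of the gradient matrix below `1e-3` per pixel), points that leave the
image, fail to converge, or end with a mean squared residual above `0.02`
(on the 0-1 intensity scale) are flagged invalid. These tracker settings
are package defaults, stated here because the underlying protocol does not
pin them down; all are configurable through `trackingConfig()`.

The per-point displacements are projected onto the ROI axis and summarized
by an ordinary least-squares line,

```
displacement_i = translation + epsilon * (position_i - centroid),
```

whose slope `epsilon` is the frame-to-frame *strain increment* -- a linear
strain model along the fiber direction. An optional trimmed variant
(`robustFit = TRUE`) drops the 20% largest-residual points once and
refits. ROI length accumulates multiplicatively,
`L[k+1] = L[k] * (1 + epsilon[k+1])`, which keeps the bookkeeping identity
`prod(1 + epsilon) = L_n / L_0` exact and avoids the additive drift that
accumulates when increments are summed. Frames with fewer than
`minValidFraction` (default one half) valid points carry the previous
length forward and stay masked; more than `maxInvalidRun` (default 10)
consecutive masked frames abort with a tracking-lost error, because a
re-acquired pattern can no longer be trusted to be the same tissue.

### Deformation, rate, and the analyzed cycle

Deformation is the percentage length change against the reference frame,
`d_k = 100 (L_k - L_ref) / L_ref`, elongation positive, shortening
negative -- this sign convention is fixed package-wide. The reference frame
is the first frame of the analyzed cycle (the midline start event): the
protocol defines deformation "compared to rest" without pinning the rest
frame, and the cycle start is the only frame of the analyzed segment where
the muscle is demonstrably back at its resting length; the choice is a
`referenceFrame` argument, so any other convention is one call away.

The deformation rate (`%/s`) is the centered finite difference of the
curve (one-sided at the segment ends); a rate sample is masked whenever
any deformation sample in its stencil is masked. No smoothing is applied
by default because none is part of the emulated protocol.

`segmentCycle()` cuts the half-open frame interval `[start, stop)` of the
requested rotation out of the sync channel and refuses to guess when the
start/reach/stop triplet is incomplete -- segments must begin and end on
sync events, never mid-cycle.

### Area statistics and the 25-variable feature table

Each muscle/direction curve is summarized by trapezoidal areas. The
trapezoid rule `A = (t/2)(y_1 + 2 y_2 + ... + 2 y_{n-1} + y_n)` is applied
after inserting, by linear interpolation, an extra sample at every
crossing of the 0% line, so that elongation (above 0%) and shortening
(below 0%) areas can be accumulated separately and exactly:

* `above` -- elongation area (`%*s`, >= 0),
* `below` -- magnitude of the shortening area (>= 0),
* `total = above + below` -- total deformation area,
* `diff = above - below` -- equal to the signed integral of the curve,
* `raterms` -- root-mean-square of the valid rate samples (`%/s`).

`total` is the *sum of magnitudes*, not the signed integral: the
total-deformation quantity of interest counts elongation and shortening
as activity of the same sign. The variable names "over curve"/"under
curve" used in the clinical literature map to `above`/`below` here; the
mapping is fixed in the feature-table schema sidecar. For piecewise-linear
curves sampled at their breakpoints the decomposition is exact to machine
precision (a tested invariant), and on smooth curves the error falls as
`O(dt^2)`.

Five muscles times five statistics give the 25 feature columns of the
feature table (one row per subject x timepoint x direction, metadata
columns for group, sex, age, WAD grade, timepoint and direction). Rows
missing any muscle are rejected with a logged reason rather than imputed.

## The synthetic cohort

### What the generator emulates

`renderSequence()` draws a uniform scatterer field (default 25 scatterers
per mm^2, amplitudes `|N(1, 0.35)|`), advects it analytically, splats it
onto the pixel grid with bilinear weights and convolves with a Gaussian
point-spread function (default sigma 0.12 mm axial x 0.25 mm lateral,
matching the resolution scale of a 12 MHz linear array), then quantizes to
8-bit at 50 frames/s with 0.15 mm pixels -- the acquisition geometry of the
emulated protocol. Within each layer the along-fiber coordinate is
stretched by `1 + s_l(t)` about the image center, with linear
through-depth blending across the 0.4 mm fascial gaps and a 1 mm taper to
zero outside the muscle stack; because frames are rendered directly from
the advected scatterers (never by resampling a rendered image), the
integrated stretch over any in-layer segment equals the prescribed strain
exactly, and `advectPoints()` reproduces the ground-truth curves to below
`1e-6` percentage points.

The motion model prescribes `nCycles` identical out-and-back rotations.
The default cycle period is 2 s; the metronome instruction underlying the
protocol (30 beats/min, reach on one beat, return on the next) is
ambiguous between 2 s and 4 s per full cycle, and 2 s was fixed as the
package default -- it only scales the time axis and the `%*s` units, not
any comparison made on equal terms. Two waveforms are available: a
raised cosine (one-signed, peaking at the 20-degree reach exactly
mid-cycle) and a biphasic shape with a shortening undershoot (default
undershoot ratio 0.3) that populates both area lobes; cohort simulation
defaults to the biphasic shape for that reason. Rest frames prepended
before the first cycle carry exactly zero motion. Additive sensor noise
(SD 0.02) uses a *static* field by default -- one drawn noise pattern
shared by all frames -- so that a motionless phantom yields bit-identical
frames; `noiseMode = "temporal"` provides per-frame noise for robustness
experiments. An optional rigid sinusoidal translation (probe sway) can be
superimposed to stress the rigid-motion null.

### Cohort effect structure

`CohortConfig` holds mean strain amplitude per (group, muscle, direction).
The default map emulates the qualitative case-control structure the
package targets: controls share one amplitude profile (3.5-7.5% from TR
down to MF) in both directions, while the WAD group's three deepest
muscles (Scap, Scerv, MF) are reduced by 2 percentage points in right
rotation (the most painful side) only, with a 1.5-point recovery at
follow-up. Between-subject variability is a total SD of 1.5 percentage
points per amplitude, split evenly (correlation 0.5) between a
subject-shared and a muscle-specific component, giving the
compound-symmetry-like covariance repeated-measures models expect. The
study's true per-muscle strain magnitudes are unknown (they are not
published as numbers), so these defaults are free parameters chosen once
at physiologically plausible scale; every accuracy claim in the tests is
*parameter recovery* against the generator's own ground truth, not a
comparison to clinical values.

`simulateFeatureTable()` is the statistics-level path: it draws the
per-subject amplitudes and converts them into feature rows through the
same deformation-curve and area code as the imaging path, using the exact
one-cycle curve implied by each amplitude. Because those curves are exact
scalings of one waveform, the five statistics of a muscle are perfectly
correlated at the statistics level -- a deliberate simplification that
imaging-level tables do not share (tracking noise decorrelates them).
Passing tests therefore demonstrate the inference machinery's operating
characteristics under a known, idealized feature model, not the noise
structure of clinical curves.

## Inference

### Univariate models

`mixedAnova()` fits the split-plot design -- group (between) x muscle
(five within levels) -- through `stats::aov` error strata, with sex
entered as an *additive between-subject factor* when `adjustSex = TRUE`.
"Adjusted by sex" could equally mean a covariate; the factor coding was
chosen because sex is categorical here, and the flag makes the adjustment
explicit and removable. Sphericity of the within factor is tested with
Mauchly's W computed from the orthonormal-contrast covariance pooled
within between-subject cells (the chi-square approximation including the
second-order term, matching `stats::mauchly.test`); when `p < 0.05` the
Greenhouse-Geisser epsilon -- `tr(A)^2 / (m tr(A^2))` on the same contrast
covariance, bounded in `[1/m, 1]` -- rescales the within and interaction
degrees of freedom. Effect sizes are partial eta-squared,
`SS_effect / (SS_effect + SS_error)` within each stratum. Sums of squares
below a numerical floor are treated as exactly zero so degenerate designs
report `F = 0, p = 1` instead of 0/0 artifacts.

`posthocLevelContrasts()` collapses the five muscles to three anatomical
levels (superficial TR/SP, middle Scap, deep Scerv/MF), computes each
subject's pairwise level difference and tests its group effect -- the
level x group interaction contrast -- for the three level pairs, with
Bonferroni correction over that family of three (the family definition is
the package's, made explicit here because "with Bonferroni correction"
does not itself define one). `withinSubjectAnova()` fits the fully
within-subject timepoint x muscle design for paired subjects, each within
effect with its own error stratum and its own sphericity assessment on
its own contrast set (Kronecker products of the factor contrasts).

The significance threshold is 0.05 throughout, with GG correction applied
conditionally on Mauchly `p < 0.05`, and p-values come from the F
distribution; no permutation variant is provided.

### Multivariate models

`fitPCA()` wraps `stats::prcomp` on the mean-centered, unit-variance
matrix (the scaling convention of the SIMCA software family; disable with
`scale = FALSE`) with a deterministic sign convention. `fitOplsDa()`
implements two-class OPLS-DA: a centered 0/1 response, `nOrthogonal`
components uncorrelated with it split off first (default 1 -- the
smallest model that separates predictive from orthogonal variation; the
count is configurable because nothing in the emulated analysis states
it), then a single predictive component. With `nOrthogonal = 0` the model
provably collapses to 1-component PLS-DA, which is cross-checked against
an independent PLS implementation in the tests.

`crossvalidateJackknife()` partitions subjects into 7 class-stratified
folds -- leave-out-p with p of about one seventh of the subjects -- fits a
sub-model per left-out fold, sign-aligns the sub-model loadings to the
full model and forms a delete-group jackknife standard error per
variable. The confidence interval is `loading +/- t * SE` with the
t-quantile at `nFolds - 1 = 6` degrees of freedom at 95%; a variable is
flagged significant when its interval excludes zero. Fold assignment is
seeded and recorded, so a fixed seed reproduces folds, intervals and
flags bit for bit. Held-out predictions give the cross-validated
accuracy; no attempt is made to reproduce proprietary SIMCA diagnostics
beyond it.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based (row, col), converted to mm via the pixel
  spacing; every writer states this in its header or schema.
* Curves with all samples masked, reference frames that are masked,
  fewer than two valid samples, single-class OPLS-DA inputs, and
  missing-cell ANOVA designs all raise errors; nothing is imputed
  silently.
* Zero-variance feature columns are dropped (with a message) before
  multivariate modelling; raised-cosine phantoms genuinely produce such
  columns (`below` is identically zero when a curve never shortens).
* Samples exactly at 0% are treated as crossing points themselves; no
  extra sample is inserted around them, and zero-length sub-intervals
  contribute zero area.
* Test and example problem sizes (200 x 160 px scenes, 2-cycle motions,
  cohorts of 34 per group at the statistics level, 2000-replicate null
  studies) are the package's chosen balance between statistical
  resolution and runtime on a single CPU.

## Known limitations

* The tracker exhibits the classic pixel-locking bias of window-based
  speckle tracking: peak deformation is underestimated by roughly 5% of
  its value at large strains (about 0.8 percentage points at a 10% peak).
  This is within the package's stated recovery tolerance of
  `max(0.5 pp, 10% relative)` and is reported here rather than hidden by
  post-hoc calibration.
* The image model is a 2-D scatterer field with a Gaussian PSF: no RF
  physics, no out-of-plane motion, no probe-pressure artifacts, no
  attenuation or shadowing. It exercises the *tracking* problem, not the
  acoustics.
* Statistics-level features are exact functionals of one waveform, so the
  five statistics of a muscle are collinear there (see above).
* The univariate module covers the classical split-plot F tests; no
  mixed-effects (REML) alternative is provided.
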