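# SpeckleStrain

Speckle-tracking deformation analysis of dorsal neck-muscle ultrasound, for
researchers studying mechanical muscle function in neck pain (e.g. chronic
whiplash-associated disorders, WAD) and for methods work on
ultrasound-based strain estimation.

During a paced 20-degree head-rotation task, B-mode video (50 frames/s,
12 MHz linear array geometry) shows five stacked dorsal neck muscles --
trapezius (TR), splenius (SP), semispinalis capitis (Scap), semispinalis
cervicis (Scerv), multifidus (MF). The speckle pattern of each muscle is
followed frame by frame, and the package turns that motion into
deformation statistics and group-level inference:

* **Tracking.** A 15 mm region of interest (ROI) with evenly spaced
  measuring points per muscle; pyramidal Lucas-Kanade point tracking, then
  a least-squares *linear strain model* along the ROI axis,
  `u_i = c + epsilon (x_i - x_bar)`, whose slope `epsilon` is the
  frame-to-frame strain increment. ROI length accumulates as
  `L_{k+1} = L_k (1 + epsilon_k)`.
* **Curves.** Deformation `d_k = 100 (L_k - L_ref)/L_ref` (%; elongation
  positive) and its finite-difference rate (%/s), segmented to one
  rotation cycle via the contact-switch sync channel.
* **Areas.** Trapezoidal areas `A = (t/2)(y_1 + 2y_2 + ... + y_n)` split
  at the 0% line with linear-interpolated crossings: elongation area,
  shortening area, their total and difference, plus the RMS deformation
  rate -- five statistics x five muscles = the 25-variable feature table.
* **Inference.** Mixed-design repeated-measures ANOVA (group x muscle,
  sex-adjusted) with Mauchly's sphericity test, Greenhouse-Geisser
  correction, partial eta-squared and Bonferroni post-hoc contrasts over
  three muscle levels (superficial/middle/deep); PCA and two-class OPLS-DA
  with stratified leave-out-p (7-fold) cross-validation and jackknife
  confidence intervals on the predictive loadings.
* **Synthetic cohorts.** A speckle-phantom renderer with exact ground-truth
  layer strain and a cohort simulator with configurable group/muscle/
  direction effects, so the whole pipeline is testable without clinical
  data (which cannot be redistributed).

## Worked example

```r
library(SpeckleStrain)

## render a phantom with the default five-layer geometry and track one muscle
scene   <- SceneConfig(imageSize = c(200L, 160L), seed = 7L)
phantom <- renderSequence(scene, defaultLayers(),
                          MotionModel(nCycles = 2, restFrames = 10))
phantom$sequence
#> FrameSequence: 211 frames of 200 x 160 px, 50.0 fps
#>   pixel spacing 0.150 x 0.150 mm, 6 sync events

tracked <- trackSequence(phantom$sequence, defaultROIs(phantom$sequence)$Scerv)
tracked
#> TrackedROI 'Scerv': 211 frames, 211 valid
#>   length 15.00 -> 15.00 mm (range 15.00-15.99)

seg   <- segmentCycle(phantom$sequence, cycleIndex = 2)
curve <- toDeformation(tracked, referenceFrame = seg$start, frames = seg$frames)
decomposeAreas(curve)
#> AreaDecomposition 'Scerv': above 6.639, below 0.000, total 6.639, diff 6.639 %*s; RMS rate 7.362 %/s
```

The semispinalis cervicis ROI stretched from 15 mm to a 15.99 mm peak --
a 6.6% peak elongation against the 7% ground-truth amplitude of that
layer -- and, with the default one-signed waveform, all deformation area
lies above the 0% line.

```r
## statistics-level cohort (34 per group) with the default planted effect:
## reduced deep-muscle deformation in WAD, right rotation only
tab   <- simulateFeatureTable(CohortConfig(nPerGroup = 34, seed = 1))
right <- tab[tab$direction == "right", ]
mixedAnova(right, dv = "total")[, c("effect", "df1", "df2", "F", "p", "eta_p2")]
#>         effect df1 df2      F        p  eta_p2
#> 1          sex   1  65  0.541 4.65e-01 0.00825
#> 2        group   1  65 19.034 4.69e-05 0.22651
#> 3       muscle   4 264 93.746 1.67e-49 0.58684
#> 4 group:muscle   4 264 24.757 2.03e-17 0.27278

crossvalidateJackknife(as.matrix(right[, featureColumns()]), right$group,
                       seed = 1)
#> OplsDaCv: 7 folds, CV accuracy 88.2%, 15/25 significant variables
```

The group main effect and the muscle-by-group interaction are recovered,
and the OPLS-DA jackknife flags exactly the 15 variables belonging to the
three deep muscles whose amplitudes were reduced.

`runPipeline(pipelineConfig(...), outDir)` chains all stages -- simulate,
track, curves, areas, feature table, ANOVA/post-hoc, OPLS-DA -- writing
per-stage CSV/TIFF/JSON artifacts and a checksummed run manifest.

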