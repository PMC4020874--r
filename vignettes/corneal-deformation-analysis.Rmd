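---
title: "Measuring corneal deformation dynamics in air-puff tonometry sequences"
author: "corneadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring corneal deformation dynamics in air-puff tonometry sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneadyn)
```

## The measurement problem

A non-contact (air-puff) tonometer fires a brief air pulse at the cornea and
films the corneal cross-section with a high-speed Scheimpflug camera: a
typical acquisition is an `M x N x I = 200 x 576 x 140` stack of grayscale
frames, one frame every 231 µs (about 32 ms of record).  The instrument
itself reports applanation-based quantities (intraocular pressure, deflection
amplitude at the apex).  Two biomechanically interesting components of the
response are, however, entangled in the raw image sequence:

* the **whole-eyeball retro-displacement** — the globe recoils in the orbit
  under the pulse, carrying the cornea with it, and
* the **corneal deflection proper**, on which fast (150–500 Hz)
  flexural oscillations of the corneal shell are superimposed.

`corneadyn` separates these components from the image sequence alone,
quantifies the fast oscillations, condenses each eye into three dynamic
features `(w1, w2, w3)`, and classifies eyes into four deformation classes
with an unpruned Gini CART tree.

## Coordinate and intensity conventions

A sequence is an array indexed `(m, n, i)`: `m` = image row, growing
*downward* (toward the eye interior), `n` = image column, `i` = frame.
Intensities are normalized to `[0, 1]` so that threshold parameters are
scale-free.  All derived maps (contour, deformation, …) are `N x I`
matrices — rows indexed by image column, columns by frame — with positive
deformation meaning displacement into the eye.  Row/column/frame indices are
1-based throughout; missing contour detections carry an explicit `NA`
marker (0 is a valid row).

The frame interval deserves a note: the package default is 231 µs.  On a
140-frame record this gives a spectral bin spacing of 30.9 Hz, which is the
only spacing under which the feature `w2`'s FFT window (1-based bins 7–15)
corresponds to the physical 150–500 Hz oscillation band; it also matches the
~4300 frames/s rate of the instrument class being emulated.  The value is
configurable wherever it enters a computation.

## Stage 1 — pre-processing and the outer corneal edge

The raw stack is median filtered with a 3×3×3 voxel mask (edge replication
at all borders).  The mask size matters: it is the largest that removes
sensor salt noise without erasing the thin bright corneal band.

Two independent detectors then locate the outer (anterior) corneal edge in
every frame:

1. **Column-wise Otsu route** (`extract_edge_otsu`).  Each image column is
   binarized at `v_r · p_r(n, i)` where `p_r` is the column's Otsu threshold
   (256-bin histogram, exhaustive between-class-variance maximization) and
   `v_r = 0.5` is a correction for the very high contrast the corneal edge
   can reach.  The binary frame is eroded with a 3×3 element and XOR-ed with
   itself, leaving exactly the 8-connected inner boundary of the bright
   region; the contour is the topmost boundary row per column.  Bright iris
   cross-sections below the cornea are this route's known failure mode: they
   inflate the Otsu threshold.
2. **Canny route** (`extract_edge_canny`, the pipeline default).  A Canny
   edge map per frame (Gaussian σ = 0.99; high threshold 0.1 applied to the
   gradient magnitude normalized to a unit maximum, low threshold 0.4 × high),
   followed by a 3×3 morphological closing to bridge small gaps, then the
   same topmost-row rule.  The single published threshold is taken as the
   high hysteresis threshold; the 0.4 low/high ratio is the conventional
   choice.  The closing element is 2-D: mixing frames before the contour is
   extracted would smear fast motion.

A detected contour map is accepted only if **no column in any frame is
missing** and the frame-to-frame displacement of every contour point is
**below 10 px** (`validate_contour`).  Isolated failures are repaired by
within-frame linear interpolation before a 3×3 median smooths the `(n, i)`
map; a frame with no detected edge at all aborts the run rather than guess.

### Sub-pixel refinement

Both routes optionally (and by default) refine the integer topmost-row
contour to sub-pixel precision.  The intensity profile of each column is
smoothed with a vertical Gaussian (σ = 1.5 px) so the edge becomes a
well-sampled sigmoid; the crossing of the level halfway between the local
background and foreground intensity is then located by cubic (Catmull-Rom)
inverse interpolation, with the two levels re-estimated in a second pass at
fixed sub-pixel offsets (±2.5 px) from the first-pass edge so that the level
estimate does not depend on where the edge happens to fall within the pixel
grid.  On rendered phantoms this brings the contour error from the ±0.5 px
of integer quantization down to a few hundredths of a pixel, which is what
allows deflection amplitudes of 5 px to be recovered to ~1 %.  The
refinement is performed on the *unfiltered* frames when they are available
(`refine_on`): the median filter's order statistics distort the edge ramp
slightly.

## Stage 2 — separating eyeball motion from corneal deflection

The resting shape is removed by subtracting the first frame's contour,
`L_T(n, i) = L_P(n, i) − L_P(n, 1)`.  At the lateral image borders the
cornea is assumed undeformed — the air puff's footprint is central — so the
deformation observed there is pure eyeball motion.  It is extended across
the width as an affine-in-`n` field

`L_TO(n, i) = (L_T(N, i) − L_T(1, i))/(N − 1) · (n − 1) + L_T(1, i)`

and the corneal deflection is the remainder `L_TR = L_T − L_TO`.  The
implementation uses the two-weight form `(1 − t)·left + t·right` so the
border identities and the conservation `L_T = L_TO + L_TR` hold bit-exactly
in floating point; an optional averaged border band (`band_width` > 1)
trades those exact identities for robustness to border noise.  The headline
scalar `max(L_TR)` — the maximum deflection amplitude — is what the
instrument reports as deformation amplitude.

## Stage 3 — rapidly changing deformations

A flat grayscale opening with a 33×33 element (columns × frames; erosion
then dilation, replicate borders) passes the slow puff response; the
residual `L_Q = L_TR − opening(L_TR)` retains only structures shorter than
the element.  Two caveats of this classical construction are worth knowing
and are visible in synthetic data:

* a smooth pulse whose *peak region* is narrower than 33 frames has its cap
  clipped by the opening, so `L_Q` carries a low-frequency pedestal
  proportional to the pulse curvature at its peak; and
* on flanks where the slow signal's slope exceeds the oscillation's own
  slope, the opening reconstructs the ripple and `L_Q` loses it.

Both effects concern slow content and are why the spectral features below
band-limit explicitly.

`L_Q` is averaged over two lateral column bands (`[N/8, 3N/8]` and
`[5N/8, 7N/8]` — the lateral cornea, excluding both the apex and the
identically-zero border columns) to give the border signals `L_QL(i)`,
`L_QR(i)`.  Their one-sided FFT magnitude spectra (rectangular window, no
padding) and a band decomposition complete the stage: region I is `|f| <
150` Hz, region II is `200 ≤ |f| ≤ 500` Hz, reconstructed with
conjugate-symmetric masks so both components are real.  Bins in the
150–200 Hz gap belong to neither region.

## Features and classification

* **w1** — the maximum of the pattern error
  `L_Δ = L_T − (L_TO(N/2, i) + opening(L_TR))`: the largest deviation of
  the response from the eye's own apex-referenced pattern.  It is dominated
  by eyeball *tilt* (border motion not captured by the apex column), in
  pixels.
* **w2** — the maximum of the two magnitude spectra over 1-based FFT bins
  7–15, i.e. the 150–500 Hz window at 231 µs/frame.  Magnitudes are
  unnormalized (no division by `I`), which fixes `w2`'s absolute scale.
* **w3** — the duration of the fast oscillation: the envelope `e(i)` is the
  pointwise maximum over the left/right region-II components (rectified
  value by default, analytic/Hilbert magnitude as an option) and
  `w3 = last − first + 1` over the frames with `e(i) ≥ 0.8·max(e)`.
  Because the span runs between the *first and last* crossing, interior
  rectification dips are harmless.  Two estimator properties matter when
  interpreting `w3`: a band-limited reconstruction of a hard-gated burst
  smears the gate edges by a few frames (the 300 Hz-wide region II cannot
  resolve sharper transitions), so durations of hard-gated oscillations read
  a few frames short; and with only ~2 oscillation cycles per burst any
  envelope estimate is phase-sensitive at the edges.  For smoothly growing
  and decaying oscillations — the physiological case — the rule is stable.

`train_cart` induces the classifier exactly as specified for small cohorts:
greedy binary axis-aligned splits scored by weighted Gini impurity,
candidate thresholds at midpoints between consecutive sorted unique feature
values, recursion until pure leaves, **no pruning and no minimum node
size**.  Ties break deterministically (lowest feature index, then lowest
threshold); conflicting duplicate feature vectors end in a flagged impure
leaf with a lowest-label majority rule.  The package does not hard-code any
split thresholds: the four-class tree is re-induced from the bundled
ten-eye reference feature table (`eye_feature_table()`) or from synthetic
cohorts, because published trees rarely print their thresholds and the
printed feature table is the reproducible object.

## The synthetic phantom

`generate_phantom` renders fully ground-truthed sequences: a parabolic
corneal arc (bright band, thickness 25 px, smooth intensity falloff with
depth) whose contour is the sum of a raised-cosine deflection pulse
(spatially a raised-cosine bump with ≥ 20 undeformed border columns — the
separation stage's assumption), an affine-in-`n` eyeball displacement
between two border time courses, and a boxcar-gated sinusoidal ripple.
The ripple's spatial support is wider than the deflection bump (default
`min(0.9 N, N − 42)` columns): fast corneal oscillations are lateral
flexural waves, prominent off-axis where the border-signal bands sit.
Edges are rendered with linear coverage interpolation so the true contour
is a sub-pixel quantity, plus optional bright iris-like bands (the known
failure mode of the Otsu route) and clipped additive Gaussian noise.  A
fixed seed reproduces a phantom byte for byte.

Default kinematics were chosen once to emulate the instrument's conditions:
deflection onset at frame 20 with a 100-frame raised-cosine pulse (the puff
response occupies most of the record, with gentle flanks — a pulse much
shorter than that is both unphysiological and pathological for the opening,
see stage 3), eyeball ramp from frame 35 over 80 frames, ripple gate frames
45–95 at 300 Hz.  What the phantom does *not* emulate: optical Scheimpflug
distortion, specular highlights, eyelashes, tear-film reflexes, pupil
texture, or any fluid–structure physics of the puff.  Passing closed-loop
tests therefore demonstrates the *algorithm's* correctness on geometry it
was designed for, not clinical performance on patient data.

`generate_cohort` samples per-class parameter ranges (class 1: strong
eyeball tilt 34–44 px with weak ripple; class 2: weak tilt 8–14 px, weak
ripple; class 3: weak tilt, strong ripple 2.5–4 px; class 4: strong tilt
and strong ripple) so the measured features are axis-separable — the same
qualitative structure as the four observed deformation classes.

## Numerical choices and degenerate inputs

* Otsu: 256 bins over `[0, 1]`; the lowest maximizing candidate wins;
  constant input is a degenerate-input error; a constant *column* simply
  yields a missing contour marker.
* All median/morphology operators use clipped windows, which for flat
  elements equals edge replication; opening therefore stays anti-extensive
  everywhere including borders.
* Spectra require `I ≥ 16`; shorter records error out rather than return
  meaningless bins.
* An all-zero `w3` envelope returns 0 frames.
* Analysis is fully deterministic; randomness exists only in phantom
  generation and is always seed-controlled.

## Problem sizes used in the shipped checks

The package's own test suite runs closed-loop recovery on reduced phantoms
(120 × 192 and 200 × 288 columns, always 140 frames so the spectral
arithmetic is the real one) and exercises the full 200 × 576 × 140 geometry
in the amplitude-recovery and contour-fidelity acceptance checks (30 and 1
phantoms respectively); `scripts/acceptance.R` regenerates the 30-phantom
amplitude study at full size.  A full-size phantom analysis takes on the
order of 10 s on one CPU core.

## Known limitations

* The `*.cst` vendor container is not parsed; sequences must arrive as
  multi-page TIFF or per-frame PNG/TIFF directories.
* Only the outer (anterior) corneal edge is modelled; no pachymetry.
* The eyeball model is a per-frame affine displacement across the width —
  no rotation, no out-of-plane motion.
* `w2` is in unnormalized FFT magnitude units; comparisons are only
  meaningful at a fixed record length.
* Harmonics above ~2 kHz are outside the band this sampling can resolve.
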