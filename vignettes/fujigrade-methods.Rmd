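---
title: "Grading apples by machine vision and NIR chemometrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading apples by machine vision and NIR chemometrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fujigrade)
```

`fujigrade` implements an automatic grading workflow for near-round fruit
such as the Red Fuji apple: three appearance classifiers measured from a
top-view RGB image, a soluble-solids (°Brix) prediction model built from
400–1000 nm diffuse-reflectance spectra, and a comprehensive decision rule
that combines them into a four-level quality grade plus a four-level size
grade. This vignette explains the models, the tunable parameters, the
synthetic-data generators that stand in for physical fruit, and the design
choices made where the methods admit more than one reasonable reading.

## 1. Appearance measurement

An input image is assumed to show a single fruit on a light, low-saturation
background (a light box with a ring illuminator). The measurement chain is:

1. **Gamma transform** (`gamma_correct()`, default exponent 1.2) for
   contrast, then **Gaussian smoothing** (`gaussian_smooth()`, default
   sigma 1.0 px) for sensor noise. Smoothing is a separable convolution
   with a kernel truncated at three sigma; the image border is handled by
   half-sample mirror reflection, which makes the smoothing operator
   symmetric so that both constant images and total intensity are
   preserved exactly.
2. **Segmentation** (`segment_fruit()`): the image is converted to HSV and
   pixels with saturation ≤ 0.40 and value ≥ 0.60 are labelled background;
   the complement is the fruit candidate region. Morphological opening
   then closing with a disc of radius 3 px removes small discrete
   components and boundary interference, and interior holes — specular
   highlights, the fruit tip — are filled. The saturation/value bounds and
   the defect threshold below are not physical constants; they were fixed
   once against the package's own synthetic renderer (Section 4) by
   minimizing the measurement bias of the diameter and defect ratio, and
   they are all exposed in `vision_config()` for recalibration against a
   real camera.
3. **Contour extraction** (`largest_contour()`): connected components are
   labelled with 8-connectivity and the largest is traced by Moore
   boundary following (via EBImage). Coordinates are 1-based with
   x = column and y = row, matching both R's indexing and the moment sums
   below; contour points are pixel centres.
4. **Statistics**: the defect pixel ratio *t* (dark-pixel count inside the
   fruit over fruit pixel count, with "dark" meaning Rec. 601 luminance
   below 55 of 255), the aspect ratio λ (maximal horizontal extent of the
   contour over maximal vertical extent), and the maximum cross-sectional
   diameter in pixels `Wp = 2·max r_k`, where `r_k` is the distance from
   the moment centroid `(m10/m00, m01/m00)` to the contour. Because the
   farthest boundary point from any interior point is a convex-hull
   vertex, `r_k` is evaluated only on hull vertices; a test verifies the
   shortcut against brute force over all boundary points.

The classifiers are fixed threshold rules:

* **Defect**: *t* ≥ t₀ = 0.0018 ⇒ defective. t₀ is the area ratio of the
  smallest spot judged visually objectionable (3 mm) on a median 70 mm
  fruit: (3/70)² ≈ 0.18 %.
* **Shape**: λ in the half-open band [0.98, 1.05) ⇒ nearly round,
  otherwise nearly oval. The underlying written rule is ambiguous about
  whether λ = 0.98 itself is round; the package follows the prose
  formulation (round includes 0.98, excludes 1.05) and exposes the band in
  `vision_config()`.
* **Size**: Wp ≥ 164 px ⇒ extra-large, [139, 164) large, [127, 139)
  medium, below small. These thresholds come from inverting the reference
  pixel-to-millimetre calibration `Wr = 0.4052·Wp + 13.5015` (millimetres;
  the national-standard cutoffs are 80/70/65 mm) and rounding to the
  nearest pixel. `fit_size_calibration()` refits the line from caliper
  pairs for any new optical geometry, and `size_thresholds()` regenerates
  the pixel cutoffs. Note the units: the calibration maps pixels to
  millimetres, not centimetres — the published pixel thresholds only
  reproduce under that reading.

## 2. Brix prediction

Reflectance spectra are corrected against white/dark references
(`reflectance_correct()`, `R = (I−I_d)/(I_w−I_d)`), decimated keep-one-in-
three from 1771 to 591 wavelengths (`downsample_wavelengths()`; the
decimation counts determine the stride — "every two points" skipped),
then scatter-corrected. Multiplicative scatter correction regresses each
spectrum on the set mean and inverts the fitted affine distortion; the
standard normal variate transform standardizes each spectrum to zero mean
and unit variance. The order MSC→SNV is the package default; both steps
are optional flags in `fit_brix_model()` because the source procedure does
not state whether they were composed or compared.

Samples are partitioned 3:1 into calibration and prediction sets by SPXY
(`spxy_split()`): Kennard–Stone farthest-point accretion on the joint
distance `d_xy = d_x/max d_x + d_y/max d_y`, with Euclidean `d_x` on the
preprocessed spectra and absolute difference `d_y` on Brix. The component
metrics are a design choice — the joint-distance formula does not fix
them — and are the natural ones for a vector predictor and scalar
response.

The regression engine is single-response NIPALS PLS (`pls_fit()`), mean-
centred, no variable scaling (the spectra are already normalized by
MSC/SNV). The implementation exposes the regression coefficient vector for
every truncation 1..A of the latent components, so k-fold cross-validation
(`select_ncomp_cv()`, default 10 folds, shuffled once per seed, capped at
20 components, minimum-RMSECV rule) costs one fit per fold. In the
full-component limit PLS reproduces ordinary least squares, which the test
suite checks against the normal equations, and predictions are cross-
checked against an independent PLS implementation (mixOmics).

### Wavelength selection

**CARS** (`cars_select()`, default 50 Monte-Carlo runs) shrinks the
wavelength set competitively. Each run fits PLS on a random 80% of the
calibration samples and takes absolute regression coefficients as weights;
the subset size then follows the standard two-point exponential schedule
(all W variables at run 1, 2 at run 50). Within a run the top half of the
scheduled count is retained outright (forced retention) and the remainder
is drawn by weight-proportional sampling without replacement (adaptive
reweighting). Two literal readings of the update were rejected on
implementation grounds: sampling the scheduled count without replacement
from the force-retained set is the identity, and classic roulette
sampling with replacement shrinks the subset by a further ≈0.63× per run
on top of the schedule, collapsing it within a dozen runs instead of
exploring the full size range. The sampled-run RMSECV trace is recorded
and the minimum-RMSECV subset returned.

**SPA** (`spa_select()`) grows a candidate chain from every start column
by successive orthogonal projection — each step adds the column with the
largest norm after projection onto the complement of the chain's span —
on autoscaled columns, so the criterion compares direction rather than raw
variance. Chains are compared by 10-fold cross-validated multiple linear
regression RMSE at the maximal size, and subset sizes 30–50 are then
scored along the winning chain; scoring every (start, size) pair would
cost ~12 000 model fits per call without changing the per-step projection
property that defines the method. SPA's defining strength — minimal
collinearity — is also its limit here: if several absorption bands share
one latent amplitude, SPA keeps a single channel per collinear group by
construction (see Section 5).

`fit_brix_model()` wires these together and reports `R_c`/RMSEC on the
calibration set and `R_p`/RMSEP on the untouched prediction set;
`classify_brix()` grades predictions at ≥13 °Brix (high) and ≥10 (medium).

## 3. The comprehensive grade

`grade_apples()` is a total function over the 2×2×3 label space: any
defect ⇒ substandard; defect-free oval fruit ⇒ second class directly, its
Brix deliberately not consulted ("directly evaluated"); defect-free round
fruit ⇒ excellent / first class / second class for high / medium / low
Brix. The size grade is carried through unchanged and never feeds back
into the quality grade. An exhaustive 12-case test pins the table down.

## 4. Synthetic fixtures and what they do (not) show

**Images** (`render_apple()`): a red-hued filled ellipse on a light
background with dark defect discs (placed fully inside the fruit, overlap
allowed, area counted on the rendered raster), an optional white specular
highlight that exercises hole-filling, and mild pixel noise (SD 2 of
255). Ground truth is computed from the drawn raster with independent
code: `t` from the painted pixel counts, λ from the mask extents, `Wp`
as twice the maximal centroid-to-boundary distance of the drawn mask.
`appearance_benchmark()` renders a trial mirroring a physical validation:
half defect-free / half clearly defective (4–50× the critical ratio, as
real defective fruit are not borderline), half nearly round / half nearly
oval, and diameters spread evenly over the four size classes including
values adjacent to the 164/139/127 px boundaries.

**Spectra** (`simulate_spectra()`): reflectance = per-sample affine
scatter distortion of {smooth baseline − Brix-linked Gaussian absorption
bands − pigment interferents − visible-region clutter} plus detector
noise. Brix is drawn from Normal(11.7, 1.1²) truncated to [8.9, 14.6]
°Brix, the distribution of the reference campaign the defaults emulate.
The four narrow bands (745/842/912/962 nm, SD 2.5 nm, depths 0.008–0.012
per °Brix) sit in a quiet analytical window (710–985 nm, noise SD 0.003);
outside that window the noise SD is 7× larger, reflecting the fall-off of
CCD sensitivity toward the edges of a spectrometer's range, and 24
broad clutter components with random per-sample amplitudes emulate
pigment variability over 420–700 nm. These defaults were calibrated once,
before freezing, to the stated goal that full-spectrum PLS be mediocre
and band-selective models win; they were not revisited afterwards.

What passing tests show: the pipeline recovers known geometry and a known
planted signal under controlled distortions. What they do not show:
performance on real fruit — real defects are not uniform dark discs, real
peel has texture and colour gradients, and real NIR spectra contain
temperature-dependent water bands and nonlinear scattering that no
affine-plus-noise model reproduces. The ≥95% classifier agreement and
`R_p ≈ 0.93` benchmarks are statements about the synthetic conditions.

## 5. Numerical choices, open points, limitations

* **Coordinates** are 1-based throughout (x = column, y = row), the
  convention of both R and the moment sums; a 0-based convention was
  considered and rejected as a source of off-by-one noise in an R package.
* **Threshold rounding**: the pixel size thresholds use round-to-nearest;
  floor would give the same published triple.
* **Ties**: the largest connected component is chosen by pixel count with
  ties broken by label order (first occurrence in scan order); `which.min`
  breaks RMSECV ties toward fewer components/earlier runs.
* **Degenerate inputs** raise classed conditions
  (`fujigrade_invalid_parameter`, `fujigrade_degenerate_*`,
  `fujigrade_no_contour`, `fujigrade_pairing_error`, ...), so callers can
  branch on failure modes.
* **Seeds**: every stochastic operation takes an explicit seed and
  restores the caller's RNG state; identical seeds give identical output,
  byte-for-byte for the renderer.
* **SPA versus full-spectrum PLS**: with a planted signal whose band
  amplitudes are exactly one latent variable, SPA retains one channel per
  collinear band group (by design) and its PLS model is then close to —
  not better than — full-spectrum PLS. The benchmark therefore asserts
  the robust ordering statement (CARS-PLS reaches `R_p ≥ 0.9` and beats
  both alternatives in ≥80% of 20 replicates; observed 18/20) rather than
  a strict three-way ranking. Breaking the band collinearity with
  per-band amplitude noise (`band_noise_sd`) lowers every model's ceiling
  without separating the middle rank, so the default leaves it at zero.
* **Problem sizes** in the shipped tests and acceptance script are the
  study's own: 168 samples × 1771→591 wavelengths, 126/42 SPXY split, 200
  rendered fruit, 20 benchmark replicates.
* **Scope**: camera/spectrometer control, conveyor synchronization and
  GUI display are out of scope; so are colour/red-coloring-rate and
  fruit-shape-index grading, which the implemented classifiers do not
  consume. Image IO is PNG-only.
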