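---
title: "Single-camera shape grading: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-camera shape grading: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiwigrade)
```

## The problem

UNECE FFV-46 grades kiwifruit by weight and by the MiDES/MaDES ratio (MMR),
the ratio of the minimum to the maximum diameter of the equatorial section:
Extra needs MMR ≥ 0.8 and ≥ 90 g, class I needs MMR ≥ 0.7 and ≥ 70 g,
class II needs ≥ 65 g, everything else is rejected. A single overhead camera
on a sorting line can measure length, MaDES and projected area (PA), but not
MiDES: a Hayward kiwifruit rolls onto its flat face, hiding the thin
diameter from a top view. `kiwigrade` estimates MiDES (and volume) from the
measurable quantities with fixed linear models, grades on the estimated
MMR, and then corrects the characteristic misgrades with linear discriminant
lines in a shape-ratio plane.

## Image measurement

The measurement pipeline is deliberately minimal, assuming the controlled
imaging of a sorting line (fixed camera height, uniform lighting, one fruit
per frame on coordinate paper):

* **Grayscale.** NTSC luminance, `0.299 R + 0.587 G + 0.114 B`. The
  formula's source does not fix a rounding rule; we round half-up to the
  nearest integer (deterministic and direction-free, unlike the IEC
  round-half-even used by `round()`).
* **Thresholding.** Otsu's criterion over the 256-bin histogram, scanning
  all thresholds and minimizing the within-class variance; ties break to
  the lowest threshold. `binarize()` maps pixels *at or above* the
  threshold to white — "below the threshold" is black, so equality goes to
  the foreground. A constant image has no valid threshold and is an error.
* **Denoising.** Connected components of white pixels are labelled
  (8-connectivity by default — diagonal contact counts, which keeps
  one-pixel-wide hair attached to the fruit; 4-connectivity is available)
  and every component strictly smaller than 1/20 of the largest is removed.
  The largest component always survives.
* **Sizing.** The minimal bounding rectangle is axis-aligned (the fruit's
  long axis is frame-aligned on a sorting line). The long side is reported
  as the length and the short side as MaDES regardless of orientation, so
  `length ≥ MaDES` always holds. An optional principal-axis measurement
  (`rotate_to_axis = TRUE`) handles rotated fruit but is off by default.
* **Calibration.** `RA` is the pixel count of one 1 mm × 1 mm grid square.
  `calibrate()` estimates the pixel pitch from the row/column mean-intensity
  profiles of a grid image: grid lines are the minority intensity side of
  the profile, line centres come from runs beyond 0.5 SD, and spurious
  centres (noise blobs) are rejected by a median filter on the spacings.
  When the geometry is known, pass `ra` directly; `measure_fruit_image()`
  self-calibrates from the top/left 12% margins otherwise.
* **Hair offset.** Surface hair is segmented as fruit, so linear sizes are
  systematically oversized by roughly twice the mean hair length
  (~0.5 mm per side for Hayward). A configurable `hair_offset_mm` can
  subtract this; it is 0 by default because the reference models were
  calibrated on uncorrected measurements.

## Estimation models

The built-in estimators are fixed linear models over (W, L, MaDES, PA), with
PA in cm² at the model interface (the imaging layer emits mm² and converts
explicitly):

* MiDES (mm) = −2.36 − 0.08 W + 0.66 L + 0.24 MaDES − 3.71×10⁻⁴ PA
* V (cm³) = −2.69 + 0.93 W + 0.09 L + 1.65×10⁻³ MaDES + 5.47×10⁻⁵ PA

Stepwise selection on the original calibration data dropped PA from the
MiDES model and PA and MaDES from the volume model, but only the
four-predictor coefficient tables are published. The built-ins therefore
carry **all** published coefficients rather than inventing refitted
three-predictor values: the dropped terms are numerically negligible
(≈0.01 mm and ≈0.002 cm³ at typical sizes), and using only printed numbers
keeps the estimators reproducible.

`fit_smlr()` re-derives such models on new calibration data: forward entry
by the smallest t-test p-value below `alpha_enter` (default 0.05), backward
removal of any selected predictor above `alpha_remove` (default 0.10),
iterated to a fixed point, with a final OLS refit on the selected set.
Collinear candidates whose entry makes the design singular are skipped.
Degrees of freedom follow the usual residual convention (n − k − 1). In the
support-recovery experiments of the test suite the entry threshold is
tightened to 0.01: with two pure-noise candidates and the default 0.05, the
chance that *some* noise variable clears the bar is ≈ 1 − 0.95² ≈ 10% per
replicate by multiple testing alone, which says nothing about the selector
and everything about the thresholds; 0.01 brings the family-wise false-entry
rate to ≈ 2%.

## Grading and confusion analysis

`assign_grade()` walks the classes from Extra down and returns the first
whose weight *and* MMR requirements are met; all thresholds are inclusive
("0.8 or greater", "minimum weight"). A fruit under 65 g is Reject no matter
its shape. Grades form an ordered factor (Reject < II < I < Extra), which
defines *overgrading*: an estimated class above the actual one, the
economically critical error. `build_confusion()` tabulates estimated by
actual classes; `classification_rate()` is the diagonal share (reported to
one decimal, as grading rates usually are) and `overgrade_count()` the mass
strictly above the diagonal.

## Ratio-space reclassification

MiDES estimation error concentrates misgrades in the estimated Extra and I
groups, and the affected fruit are mostly flattened: heavy fruit whose
inflated MaDES puts the true MMR below its class threshold while the
regression — anchored on typical shape — overestimates their MiDES. In the
(length/MaDES, length/PA) plane such fruit sit visibly below the well-formed
cloud, so linear boundaries can reassign them.

`fit_discriminant()` is the textbook equal-covariance two-class discriminant
in closed form: `w = S⁻¹(m₁ − m₂)`, cutoff `w·(m₁+m₂)/2 − log(n₁/n₂)`
(empirical priors by default, equal priors on request). It is cross-checked
against `MASS::lda` in the test suite. Points exactly on a line are
assigned to the lower grade — conservative, and configurable.

`fit_reclassifier()` assembles the line set the grading study needs: within
estimated Extra one line (actual I vs actual Extra), within estimated I two
lines applied in order (actual II vs rest, then actual Extra vs rest; the
first line that votes a fruit out of its context wins). Estimated II and
Reject are never touched, and reclassification is idempotent for a fixed
line set.

One design choice matters here. A prior-weighted LDA cutoff is the
error-optimal *Gaussian* boundary, and with a minority group at Mahalanobis
distance ~1.7 and prior odds ~1.8 it simply assigns everything to the
majority — the reclassification step would silently do nothing. In
practice such separating lines are placed by looking at the scatter and
minimizing the misclassifications they cause. `fit_reclassifier()` codifies
exactly that: it keeps the LDA *direction*, slides the cutoff to the
position with the fewest training misclassifications (ties resolve to
moving fewer fruit), and keeps a line only if it strictly reduces the
errors in its context — so reclassification never hurts on the data the
lines were fitted to, and the no-op is explicit rather than accidental.
`tune_cutoff = FALSE` restores the plain LDA cutoffs. Note the improvement
guarantee is resubstitution (lines are fitted and applied on the same
validation set, as in the original study); held-out behaviour is what the
seeded end-to-end tests measure.

## The synthetic-data generator

The generator exists so every stage has ground truth. It emulates the
acquisition setup, not fruit photography:

* **Images** (`render_fruit()`): a superellipse silhouette
  (`|x/a|ⁿ + |y/b|ⁿ = 1`, n ≥ 2) with an optional hairy boundary — a
  clamped two-tone sinusoid of the boundary angle with seeded random
  phases, amplitude = maximum hair length in mm — rendered bright on dark
  coordinate paper with a 1 mm grid, Gaussian pixel noise, and optional
  bright noise blobs placed clear of the fruit. Ground truth is computed
  from the boundary curve by quadrature (area = ½∮R(θ)²dθ), not from
  pixels: the true projected area includes the mean hair contribution,
  while the true length/MaDES are the fruit proper (2a, 2b) so the hair
  oversize bias is measurable. For a noiseless ellipse the quadrature
  reproduces πab to numerical precision, and pixel-counted areas agree
  within 3% for RA ≥ 25.
* **Populations** (`sample_population()`): per-class truncated multivariate
  normal draws of (W, L, MaDES, MiDES, PA, V) matching the reference means
  and SDs of the 490-fruit Hayward table, under a fixed correlation
  convention. The joint distribution of real fruit is not published, so the
  correlations are a design choice: linear sizes are strongly coupled
  (L–MaDES 0.95, MaDES–MiDES 0.95), PA tracks the L×MaDES footprint, and
  volume tracks weight (density ≈ 1 g/cm³). The tight size coupling is what
  gives within-class shape-ratio SDs of ~0.04 — the level the reference
  ratio table reports — and it encodes the biological fact that shape
  deviation in Hayward fruit is essentially flatness, not free variation of
  one diameter. We considered deriving PA and V structurally
  (PA ≈ κ·L·MaDES, W ≈ ρ·V); matching both the means *and* SDs of all six
  published marginals that way is over-determined, so the MVN convention
  was preferred, with the structural relations retained for the flattened
  rows below.
* **Flattened subpopulation**: heavy fruit (sampled W ≥ 90 g) in generating
  classes I and II get their MaDES inflated until the MMR lands in the
  class's shape band (0.70–0.80 for I, < 0.70 for II), with PA and V
  recomputed from the new footprint. This is a definitional necessity, not
  a tuning knob: a class I/II fruit with Extra-level weight is in the lower
  class *because* its shape disqualifies it, so heavy round draws would be
  fruit the class definitions rule out. About 31% of class I and a third of
  class II end up flattened, matching the reported shares of
  heavy-but-flat fruit.
* **Labels**: each fruit's actual class is recomputed from its sampled
  weight and true MMR. Near the thresholds this can disagree with the
  generating class — deliberately, since that disagreement is the raw
  material of the confusion analysis.

What the generator does **not** emulate: real hair texture (the boundary
perturbation is smooth, not filamentous), lighting gradients, lens
distortion, the perspective size inflation of tall fruit, colour variation,
blemishes, or the true joint distribution of fruit morphometry. Passing
tests therefore demonstrate that the pipeline's logic and numerics are
correct under the stated geometry and population model — not that the
printed regression coefficients or the 84.6%/98.3% rates would be
reproduced on real fruit, which requires the original 490 fruit.

## Numerical conventions and degenerate inputs

* Rounding: half-up for grayscale; rates reported to one decimal.
* Otsu ties → lowest threshold; thresholding equality → white.
* Area filter: *strictly* smaller than max/20 is removed (a 100-px blob
  survives next to a 2000-px fruit).
* Discriminant ties (points on a line) → lower grade.
* Degenerate inputs error loudly: constant images, empty foregrounds,
  non-positive RA, singular pooled covariance, infeasible correlation
  matrices, fruit larger than the canvas.
* Truncation of population draws (redraw until all-positive) slightly trims
  tails; with the reference SDs the effect on means is far below the 2%
  sampling tolerance used in tests.

## Problem sizes

The test suite and acceptance script use sizes chosen to make the
statistics stable while keeping a full run in the minutes range: the
end-to-end study uses the study's own 140/350 calibration/validation split;
Otsu is checked against a brute-force oracle on 125 random images; size
recovery spans a ∈ [25, 40] mm, b ∈ [20, 30] mm at RA ∈ {9, 25, 100};
stepwise support recovery runs 100 replicates at n = 500; population-moment
checks draw 4000 fruit (10⁴ would tighten the check but adds nothing at the
2% tolerance).

## Limitations

* The built-in models are calibrated for Hayward kiwifruit measured with
  this exact pipeline (hair included); other cultivars or corrected
  measurements need refitting via `fit_smlr()`.
* The MiDES model is linear; its error is systematic at the extremes
  (over-estimation for thin fruit), which is precisely why the
  reclassification stage exists.
* Discriminant lines are fitted by resubstitution, as in the original
  study; for deployment they should be validated on held-out fruit.
* The single-camera geometry assumes the fruit rests on its flat face;
  fruit standing on end would be misgraded.
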