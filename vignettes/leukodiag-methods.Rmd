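---
title: "Methods: blood-smear analysis for leukemia screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-smear analysis for leukemia screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Acute lymphoblastic leukemia (ALL) shows up in stained blood smears as
lymphoblasts: immature lymphocytes with enlarged, irregularly shaped nuclei
and coarse, lumpy chromatin, in contrast to the small, round, homogeneous
nuclei of normal lymphocytes. `leukodiag` implements a classical screening
pipeline over smear micrographs — enhancement, nucleus segmentation,
texture/color feature fusion, and two-class classification — together with a
small trainable convolutional network, a full evaluation suite, and a
deterministic synthetic smear generator so that every stage is testable
without any external image archive.

## Enhancement

Microscope illumination varies between acquisitions, so images are first
color-balanced and then sharpened by a pair of complementary filters:

* an **average filter** over a 6 × 6 window with the center pixel excluded,
  so each pixel is replaced by the mean of its 35 adjacent pixels. An even
  window has no central cell; the window covering pixel `(r, c)` spans rows
  `r−2 … r+3` and columns `c−2 … c+3` (0-based), a fixed documented
  convention;
* a **discrete Laplacian** (4-neighbor stencil `[[0,1,0],[1,−4,1],[0,1,0]]`
  by default, 8-neighbor available), whose response is large exactly at
  intensity edges such as nucleus boundaries.

The enhanced image is the smoothed image minus the Laplacian response,
clipped to [0, 255] only after the subtraction so intermediate negatives are
preserved. Borders use symmetric reflection by default (replicate and zero
padding are options). "Color balancing" is implemented as gray-world
scaling — each channel is multiplied by the ratio of the grand mean to its
own mean — because a per-channel "area" is otherwise underdetermined; it is
exposed as a switchable option (`normalize_channels(method =)`).

Both filters are applied per RGB channel by default (luminance-only is
possible by converting first); this choice is unobservable downstream for
the grayscale consumers and matters only for the color histogram.

## Segmentation

Nuclei are found by **adaptive region growing** on the luminance image.
Seeds sit on a regular grid (default spacing 16 px); a region admits an
adjacent pixel `q` while

> |I(q) − running mean| ≤ k · max(running sd, 1),   k = 2.5 by default.

Growth is breadth-first with neighbors visited in row-major order, which
makes the partition deterministic. Pixels left unassigned become new seeds,
so the partition is exhaustive by construction.

A successful segmentation must satisfy four conditions: the regions cover
the image, each region is connected, a homogeneity predicate P holds within
every region, and P fails on the union of any two adjacent regions. The
predicate attached to the growth rule is left open by the classical
formulation, and the obvious candidates fail: "max deviation ≤ k·sd of the
region itself" is unsatisfiable on realistic noisy images (the maximum
deviation of n Gaussian draws grows like sd·√(2 ln n), which exceeds
2.5·sd for n beyond a few thousand), and an absolute cap on the *standard
deviation* is insensitive to exactly the configuration that matters — a
small dark nucleus unioned into a vast bright background barely moves the
union's sd, so such a predicate lets the merge pass swallow the nucleus.
We therefore cap the intensity *range*, which any small inclusion blows
open regardless of region sizes:

> P(x) := max(I over x) − min(I over x) ≤ `range_cap`   (default 160).

After growth, a **repair pass** splits off pixels deviating more than
`range_cap/2` from their region's mean and relabels connected components —
one strip leaves the remainder inside a band of width `range_cap`, so this
terminates — and a **merge pass** joins adjacent regions whose union still
satisfies P until no such pair remains. The output therefore satisfies all
four conditions, which `check_segmentation_conditions()` verifies
directly, and the merge pass makes the result independent of how finely
the growth stage fragmented the image. The default cap of 160 sits above
the spread within a nucleus region (chromatin mottling plus the soft-edge
blend pixels, ≈ 110–145 units for blasts) and below the nucleus-to-plasma
contrast (≈ 180–210 units), so it separates the compartments without
fragmenting them; red cells and plasma, some 80 units apart, legitimately
merge into one background region.

The **ROI** is the union of regions whose mean color is nucleus-like —
saturation ≥ 0.2 and hue in the blue-purple window [200°, 320°], the band of
standard nuclear stains — with area ≥ 64 px. The mask is then refined
morphologically with a 5 × 5 box structuring element: closing, interior hole
filling (a hole is a background component with no border pixel), then
opening. Closing bridges small gaps, filling removes enclosed background,
opening deletes debris smaller than the element; the composite is
idempotent. The order was chosen because hole filling is the visible effect
the refinement must deliver; which operations the classical description
actually used, and in what order, is not fixed.

## Feature extraction (203 + 13 + 16 = 232)

All descriptors are computed strictly over the refined ROI; pixels outside
the mask never contribute.

**Local binary patterns.** Each ROI pixel with a full 5 × 5 neighborhood
inside the image is coded as Σₚ s(gₚ − g_c)·2ᵖ over its 24 neighbors
(s(x) = 1 iff x ≥ 0). The neighbors are the square 5 × 5 ring — not an
interpolated circle — enumerated clockwise from the top-left corner, outer
16-pixel ring first, then the inner 8: a fixed convention, since no bit
order is canonical. The 24-bit code range is binned into 203 equal-width
bins (`bin = floor(code · 203 / 2²⁴)`) and the histogram normalized to sum
1. No standard P = 24 histogram has 203 bins (uniform rotation-invariant
gives 26, full uniform 555); fixed-width binning is this package's
documented way to produce a 203-entry descriptor, and the bin count is a
parameter. The histogram is invariant to global additive intensity shifts.

**Co-occurrence statistics.** The luminance is quantized to 16 equal-width
gray levels; one symmetric co-occurrence matrix per direction (0°, 45°,
90°, 135°, distance 1 on axes and √2 on diagonals) is accumulated over
pixel pairs lying entirely inside the ROI and normalized to sum 1. The 13
classical Haralick statistics are computed per direction and averaged
across the four directions, yielding 13 values rather than 52 — matching
the descriptor arity. Natural logarithms, 0·log 0 = 0; sum variance is
taken about the sum average (the conventional reading of the classic
formula, whose printed reference to sum entropy is widely treated as a
typo). Which 13 statistics the classical pipeline used is not listed
anywhere; the canonical Haralick set is assumed.

**Fuzzy color histogram.** RGB is quantized into 16 coarse bins (4 × 2 × 2
over R × G × B). The default *crisp* mode is the indicator assignment —
each pixel contributes its whole unit mass to its own bin — exactly as the
classical membership equation prints it despite the "fuzzy" name. A genuine
fuzzy mode distributes each pixel's mass between its bin and the nearest
neighboring bin per channel with triangular memberships summing to 1. Both
modes return per-bin mean membership, which sums to 1 over a nonempty ROI.

The fused vector is the concatenation LBP ‖ GLCM ‖ FCH with fixed offsets
(0, 203, 216) exposed as `feature_layout`.

## Classifiers

**Perceptrons.** One multilayer perceptron serves both named presets, which
differ only in objective: `ann` minimizes the mean squared error between
the one-hot target and the softmax output, `ffnn` the cross-entropy, so
both kinds of training diagnostics (MSE curves, cross-entropy curves) are
producible. The default architecture is 232 → 10 → 2 — one hidden layer of
10 logistic units. A description of "10 hidden layers" conflicts with the
usual pattern-net reading of 10 hidden *units*; a 232-input stack of 10
sigmoid layers is untrainable with plain gradient descent, so one layer of
10 units is the default and `train_config(hidden = rep(10, 10))` exposes
the literal stack. Features are z-scored with training-partition statistics
(the raw 232 features differ by orders of magnitude in scale). Training is
full-batch gradient descent with validation-based early stopping: stop
after 6 consecutive epochs without a new validation-loss minimum (patience
6 matches the classic validation-check diagnostic) or at 1000 epochs, and
return the best-validation checkpoint, never the final epoch. The per-epoch
trace records train/validation/test loss, gradient norm and the failure
counter, which is what the loss-curve, gradient and validation-check plots
are drawn from.

**Max-margin.** The SVM is a soft-margin linear hyperplane (C = 1 — no
kernel is stated anywhere, so linear is the default) on z-scored features,
fitted via `e1071::svm`; the package stores the explicit weight vector,
bias and support-vector indices, and reports the signed distance as the
score. Tests verify the fitted margin against a coarse-to-fine brute-force
maximizer on 2-d toys.

**Micro-CNN.** The convolutional operators — cross-correlation with zero
padding and stride, ReLU, max/average pooling, inverted dropout, softmax —
are implemented from their definitions and verified against quadruple-loop
oracles. The default network conv(8@3×3)–relu–pool(2)–conv(16@3×3)–relu–
pool(2)–dense(32)–relu–dropout(0.5)–dense(2)–softmax takes 32 × 32
grayscale input (images are resized; intensities centered on mid-gray so
the first layer sees signed contrast) and is trained by mini-batch SGD with
classical momentum 0.9, learning rate 0.05, batch 16, 40 epochs — small
enough to train on a CPU in about a minute per 100 images. Dropout uses
inverted scaling so evaluation is the identity. The deep-feature tap is the
32-unit hidden activation; the hybrid mode feeds it to the max-margin
classifier, replacing the dense classification head. Convolution follows
the modern no-flip (cross-correlation) convention; the classic flipped form
differs only by kernel reversal.

## Splitting and augmentation

Per class, `round(0.2 · n)` records (round half up) are held out for
testing and the remaining pool is split 80:20 into training and validation;
with class sizes 49 and 59 this yields 31/8/10 and 38/9/12, and a 39-image
training+validation pool for the 49-image class. Augmentation expands each
training original into exactly `factor` images — the original counts toward
the factor, which is what makes 39 originals at factor 20 come out to 780
(and 47 × 17 = 799, 104 × 10 = 1040) — using rotations (90°, 180°, 270°,
±15°, ±30°), flips, crop-and-resize keeping ≥ 80 % per dimension, and
shifts ≤ 10 % of the extent. The operation families are fixed; their
parameters are this package's choices. Only training records are ever
augmented. The default handcrafted pipeline does not augment (augmentation
belongs to the CNN training phase); it is a config option.

## Evaluation

Accuracy, precision, sensitivity and specificity are the four confusion-
matrix ratios × 100, with zero-denominator cases surfacing as `NaN` plus a
warning — silent zeros would corrupt averaged reports. AUC is the rank
(Mann-Whitney) statistic with ties counted ½; the shorthand
"sensitivity/specificity" sometimes quoted for AUC is not a bounded area
measure and is not used. The error histogram uses 20 equal-width bins over
the residual range, and regression R is the Pearson correlation between
target and score.

## The synthetic smear generator

The generator emulates stained smear micrographs: a pale plasma background,
Poisson-many soft-edged red-cell discs with pale biconcave centers, and one
lymphocyte nucleus composited last, plus additive Gaussian noise (σ = 4 —
enough to exercise the enhancement stage without burying the signal).
The default canvas is 512 × 512 to keep a 200-image benchmark tractable on
one CPU; the native 2592 × 1944 of high-resolution smear cameras is
available behind a parameter. Class identity is carried by nucleus
morphology, the way blasts actually differ from normal lymphocytes: blast
nuclei draw radius from N(46, 5) versus N(30, 3), get an irregular
perturbed-polygon boundary (harmonic perturbation, amplitude 0.25·r),
sometimes a second lobe (probability 0.4), and coarser chromatin mottling
(σ = 14 versus 4). Nucleus **color** is drawn from the same blue-purple
band for both classes, deliberately: the classifier must rely on the
texture- and shape-sensitive descriptors (LBP/GLCM), not the color
histogram alone. Ground-truth masks record exactly the nucleus pixels, and
identical (parameters, seed) produce bit-identical samples.

What the generator does *not* model: staining variability between
laboratories, touching or overlapping leukocytes, platelets and debris,
focus gradients, and the L1/L2/L3 blast subtypes. Passing the synthetic
benchmark therefore shows the pipeline recovers a strong morphological
class signal end to end; it does not certify performance on real archives.

## Problem sizes and numerical choices

The built-in benchmark is 200 images (100 per class, seed 0) at 512 × 512;
the handcrafted pipeline reaches its held-out accuracy target in under a
minute of feature extraction plus seconds of training, and the micro-CNN
modes in a few minutes. Oracle-equivalence tests run on ≤ 12 × 12 images at
tolerance 1e−9. Degenerate inputs are contracts, not crashes: empty ROIs
yield zero vectors with warnings, undefined metric ratios yield `NaN` with
warnings, and a zero-variance channel is left unscaled by the gray-world
step. All randomness flows from a single seed: the pipeline derives
per-stage seeds by a stage-name hash so any stage can be re-run in
isolation, and every generator, split, initialization and dropout mask is
reproducible from the run configuration.

## Known limitations

* The 203-bin LBP layout is a documented stand-in for an unspecified
  binning; histograms with that many bins are sparse on small ROIs.
* Touching nuclei are segmented as one ROI; no watershed-style separation
  is attempted.
* The max-margin classifier is linear; no kernel search is performed.
* The micro-CNN is a desk-scale network for exercising the layer algebra
  and the hybrid topology, not a competitive image classifier.
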