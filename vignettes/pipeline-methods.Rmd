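---
title: "Methods: costophrenic-angle cropping, enhancement and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costophrenic-angle cropping, enhancement and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(cxreffusion)
```

## The problem

Pleural effusion — fluid accumulating in the pleural cavity — shows on a
frontal chest radiograph as a bright opacity filling the lower lung
field and, most characteristically, as *blunting* of the costophrenic
angle, the sharp notch where the diaphragm dome meets the chest wall.
Automated screening therefore benefits from focusing the classifier on
the band from the heart down to the costophrenic angles rather than on
the whole frame. `cxreffusion` implements that focusing as a
deterministic image-processing chain, plus the evaluation machinery to
measure whether it helps:

1. **Mask derivation** — grayscale conversion, the negative transform
   $I \mapsto 1 - I$ (lung air becomes bright foreground), fixed
   thresholding at 0.5 and morphological cleanup.
2. **Projection-profile cropping** — lateral lung boundaries from
   minima of the column-wise foreground counts, the upper boundary from
   the first threshold crossing of band-restricted row counts, the
   lower boundary from the row-count minimum in the lower half; the box
   is applied to the *original* grayscale image, the lower half kept,
   and the result resized to 227 x 227.
3. **Two-stage enhancement** — a contrast stage (histogram stretching
   by default; logarithmic and CLAHE alternates) followed by an edge
   stage (Sobel-gradient blending by default; plain thresholded Sobel,
   unsharp masking and Canny alternates).
4. **Classification and evaluation** — a pluggable backbone behind
   stratified splitting, stratified k-fold cross-validation, and
   confusion-matrix metrics.

Because clinical radiographs cannot ship with a package, a synthetic
phantom generator renders labelled frontal-CXR look-alikes with exact
ground-truth geometry, making every stage testable end to end.

## Intensity conventions

All images are numeric matrices in `[0, 1]`, row-major, with row 1 the
top of the frame; 8-bit quantization happens only at file I/O
(round half away from zero). Grayscale conversion uses the ITU-R BT.601
luma weights (0.299, 0.587, 0.114) — the generic "weighted average" with
the weights a radiology workstation would apply — and is configurable.
Thresholding uses `>=`, so ties go to foreground.

## Design choices in the mask chain

Three choices here were genuinely open, and two deserve explanation
because we deviated from the most obvious reading.

**Equalize before thresholding?** Adaptive histogram equalization (AHE,
8 x 8 tiles, unclipped) visibly improves lung-contour contrast and is
part of the preprocessing surface (`adaptive_equalize()`). However,
tile-based equalization of a *near-constant* region — flat abdomen,
collimated background — maps the tile through a degenerate histogram:
the midpoint-CDF convention sends a constant tile to 0.5, and any noise
is stretched across the full range, so a fixed 0.5 threshold converts
flat regions into dense random speckle. On piecewise-flat images this
destroys the mask. `preprocess_mask()` and `segment()` therefore
binarize the negative directly by default (`use_ahe = FALSE`), with
equalization available behind the flag for material whose tiles always
contain real structure.

**Morphological cleanup sequence.** The border policy is fixed: pixels
outside the frame are background for dilation and erosion alike. Under
that policy any sequence that *ends* in an erosion (closing does)
strips an element-radius band off foreground touching the frame border.
Those stripped border columns become spurious exact-zero minima in the
column profiles and hijack the lateral boundary search, which by
definition takes the window minimum with ties toward the edge. A
close-then-open sequence has a second defect on noisy input: dilating
first *solidifies* threshold speckle into blobs that the subsequent
opening cannot remove. The default cleanup is therefore a single
opening (disk, radius 3): it removes speckle, cannot manufacture
foreground, and leaves border-touching regions intact because it ends
in a dilation. `morph_clean()` accepts any sequence for users who want
the classical close-then-open on clean masks.

**Band restriction for the upper boundary.** The first-crossing scan
for the upper lung margin is restricted to the central third of
*columns* (the mediastinal band). The alternative reading — a central
band of rows — cannot be right for an upper margin that sits near the
top of the frame; restricting laterally keeps bright shoulder tissue
from triggering the crossing. The crossing threshold defaults to 10% of
the maximum row sum. Both are exposed in `seg_params()`.

The lower boundary takes the row-profile minimum over the lower half
with ties toward the *bottom*, so the costophrenic angle is never
cropped out. When everything below the diaphragm is exactly zero in the
profile (as on phantoms), the tie rule runs the boundary to the frame
edge; the recovered box is therefore audited by intersection-over-union
against truth rather than by exact row agreement.

## Enhancement stage

Histogram stretching maps the observed range linearly onto `[0, 1]`
(the 0-255 version of the same map is applied at 8-bit export). It is
idempotent, order-preserving and parameter-free, which is why it is the
default contrast stage: its job is to cancel per-acquisition exposure
differences, not to reshape the histogram.

The Sobel gradient stage computes both 3 x 3 kernel responses after
optional Gaussian pre-smoothing (sigma = 1 px by default), forms the
magnitude, normalizes it by its own maximum (a flat image yields an
exactly zero map), and blends `0.5 * original + 0.5 * magnitude`. The
optional steps — direction map, binary thresholding — default off and
on-demand. Two named variants cover the ablation grid: `"sobel"` is
the plain binary edge map (threshold on at 0.2, blend off) and
`"sobel_gradient"` is the magnitude blend; the two names are otherwise
ambiguous, so both variants are explicit and separately selectable. Blend weights, sigma and
the threshold are all in `sobel_config()`. Convolution uses edge
replication so ROI margins do not acquire spurious gradients; the Canny
alternate hand-implements non-maximum suppression and hysteresis
(connected weak edges are kept only when touching a strong edge)
because no installed dependency provides it.

## The phantom generator

`generate_phantom()` renders the gross intensity structure of a frontal
CXR with conventional polarity (air dark, tissue/fluid bright): a
shoulder band, a soft-tissue body whose lateral edge slants outward
with depth, two dark lung fields with rounded apices, faint rib arcs, a
bright mediastinal band with the cardiac silhouette biased toward the
image-left lung, and diaphragm domes falling laterally into sharp
costophrenic angles. With `effusion = TRUE`, the costal recess fills to
`fill_level` (a fraction of hemithorax height) with a homogeneous
bright opacity behind a Gaussian-blurred meniscus (sigma = 2 px),
blunting the recorded angle.

The slanted body edge is deliberate: each chest-wall column sees
strictly fewer extracorporeal-air rows the closer it lies to the lung,
so the lateral projection trough is *unique* and sits immediately
lateral to the lung field. That makes boundary recovery a sharp test
rather than a tie-break lottery.

Per-sample variability in `generate_dataset()` emulates acquisition
differences: fluid fill uniform in `[0.2, 0.7]` of hemithorax height
(the range from subtle to massive effusion), random effusion side,
jittered heart position, an exposure model
`gain * (I - 0.5) + 0.5 + offset` with gain in `[0.85, 1.15]` and
offset in `[-0.08, 0.08]`, and a variable linear illumination tilt.
The exposure model is what gives the contrast stage real work to do.
All randomness flows from one dataset seed through counter-derived
per-sample seeds; the same seed reproduces every image bit for bit.

What the phantom does *not* emulate: projection physics, texture,
overlapping soft-tissue gradients inside the lung, pathology other than
free-flowing effusion, patient rotation, or hardware artifacts. Tests
passing on phantoms show the chain is implemented as specified and that
its directional claims hold under controlled variability — not that the
clinical accuracies of the source setting transfer.

## Classifier backbones

The backbone interface is pluggable (`train_config(backbone = ...)`).
This build ships `tinycnn`, a desk-scale convolutional network: a fixed
seeded bank of eight zero-mean 5 x 5 filters, ReLU, 6 x 6 spatial
average pooling, a 6 x 6 pooled intensity map (324 features), and an
L2-regularized logistic readout fitted with glmnet
(`lambda = 0.01`, deterministic). The gradient-descent hyperparameters
recorded in `train_config()` (learning rate 1e-5, batch 32, 20 epochs)
are the defaults a deep backbone would use; `tinycnn`'s readout has a
closed-form training path, so they are recorded but inert for it.
Requesting a deep backbone (`efficientnet_b0`, `alexnet`, ...) raises a
capability error naming the available backbones, because no
deep-learning runtime is a package dependency.

Metric averaging defaults to macro over the two classes; on exactly
balanced validation sets macro recall equals accuracy to machine
precision, which is why balanced comparison tables show identical
accuracy and recall columns. Per-positive-class averaging is available.
Zero-denominator metrics are defined as 0 with a warning. Split sizes
round to nearest per class with the residual to training (461 per class
at 0.8 gives 369/92).

## Problem sizes and numerical choices

The shipped experiments run at desk scale, chosen so the full suite
and the reproduction script complete comfortably on one CPU: 256 x 256
phantoms; 200 phantoms for the 5-fold cross-validation check; 80
phantoms per seed, five seeds, for the enhancement ablation on hard
settings (noise sd 0.10, fill 0.15-0.30 of hemithorax). Histogram
resolution for AHE/CLAHE is 256 bins; `clip_limit` is expressed as the
maximum fraction of a tile's pixels one bin may hold (1 = unclipped),
with clipped excess redistributed uniformly. Resizing is plain bilinear
without the antialias pre-filter, which would blend frame borders
against zero padding and darken them. A constant image cannot be
stretched and is returned unchanged with a warning; a constant image
in `segment()` raises a segmentation failure, as does an all-foreground
or all-background mask.

## Known limitations

- The lower crop boundary saturates at the frame edge whenever the row
  profile has an exact-zero plateau below the diaphragm (tie toward the
  bottom). This is by design — it never crops the angle — but it makes
  the box taller than the anatomical lung field.
- `tinycnn`'s fixed filters are not learned; it is a reference
  backend for pipeline evaluation, not a clinical classifier.
- The phantom's learnability is by construction (a single
  recess-intensity threshold separates the classes at moderate fill);
  results on it bound implementation correctness, not clinical
  performance.
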