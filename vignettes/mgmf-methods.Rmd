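---
title: "Multiscale Gaussian matched filtering with neural-network fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale Gaussian matched filtering with neural-network fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmf)
```

## The problem

Coronary arteries in X-ray angiograms appear as dark, curvilinear tubes of
varying caliber on an unevenly illuminated, noisy background. Segmenting
them is conventionally split into *detection* — producing a gray-scale
vessel-likelihood map — and *segmentation* — thresholding that map into a
binary mask. This package implements both stages: a multiscale Gaussian
matched filter (GMF) whose per-scale responses are fused pixelwise by a
small feed-forward network, followed by classical histogram thresholding.

## The matched filter

A vessel's cross-sectional intensity profile is approximated by an inverted
Gaussian. The unrotated template on an odd square grid is

$$G(x, y) = -\exp\!\left(-\frac{x^2}{2\sigma^2}\right),
\qquad |x| \le \tfrac{T-1}{2},\; |y| \le \tfrac{L-1}{2},$$

where $\sigma$ is the profile spread (a proxy for vessel half-width, in
pixels), $L$ the template length along the vessel axis, and $T$ the width
at which the Gaussian trails are cut. A bank of $\kappa$ rotated copies
covers orientations $-90^\circ + i\,(180^\circ/\kappa)$; the detection
response keeps the per-pixel maximum over orientations.

Choices the formula alone does not fix, and how this package fixes them:

* **Discretization.** $L$ and $T$ are full widths on an integer grid; even
  values are rounded up to the next odd integer so templates are centred on
  a pixel. All kernels of a bank share the grid side
  $D = \max(L, T)$ (odd), with out-of-support cells at weight zero.
* **Zero-sum normalization.** The raw template is strictly negative; the
  mean over the support is subtracted so every kernel annihilates constant
  backgrounds. This is standard matched-filter practice and is what makes
  the response of a flat region exactly zero.
* **Polarity.** Because the template is a *negative* Gaussian, correlating
  the raw (non-inverted) image yields positive responses on dark vessels.
  The pipeline therefore never inverts its input, and the phantom generator
  renders dark vessels on a bright background to match.
* **Rotation.** Kernels are resampled analytically at back-rotated
  coordinates $(x,y) = R(-\theta)(u,v)$, support rectangle included. No
  image-space interpolation of the $\theta = 0$ kernel is involved, so
  every orientation is exact to machine precision.
* **Correlation, not convolution.** The kernels are symmetric under
  $180^\circ$ rotation, so the choice is immaterial, but correlation (no
  kernel flip) is fixed for reproducibility. Borders are handled by reflect
  padding, which avoids the spurious edge responses of zero padding.
* **Implementation.** Correlation runs as a circular FFT product on the
  reflect-padded plane, zero-extended to a highly composite size. The
  test suite pins this path against a quadruple-loop brute-force
  correlation at $10^{-10}$.

Named presets ship the familiar single-scale parameterizations
(`chaudhuri`: $\sigma = 2, L = 9, T = 13, \kappa = 12$; `cinsdikici`:
$\kappa = 18$; `kang`: $\sigma = 1.5, \kappa = 6$) and the multiscale
default `mgmf` ($\sigma \in \{1.5, 1.6, \ldots, 2.5\}$, $L = 13$,
$T = 15$, $\kappa = 12$). Published descriptions of the search-based
methods (`alrawi`, `gmf_evol`, `gmf_entropy`) give search spaces rather
than final values, so those presets carry documented approximations
(search-space midpoints) and are flagged `approximate`.

The scale range is stated in the source literature both as "10 values" and
as the explicit list 1.5–2.5 in steps of 0.1, which has 11 entries; the
explicit 11-value list is used here and the count is fully configurable.

## Multiscale fusion network

Single-scale matched filters favour vessels near their design width. The
multiscale stage computes one response per scale and hands each pixel's
$m$-vector of responses to a feed-forward network with two hidden layers
and one logistic output neuron — the default 11–3–8–1 design. The fused
output in $(0, 1)$ is the detection response.

Training decisions, all deliberately simple and deterministic:

* **Activations** are logistic sigmoids for hidden and output layers; the
  thresholdable output in $(0,1)$ makes this the natural choice.
* **Loss and optimizer**: mean squared error against $\{0,1\}$ labels,
  minimized by seeded mini-batch gradient descent with momentum
  (learning rate 0.5, momentum 0.9, batch 1024, 200 epochs). A full-batch
  Levenberg–Marquardt option (`optimizer = "lm"`) is provided; it is not
  the default because a single deterministic start can stall in local
  minima, whereas the stochastic default is both robust and exactly
  reproducible from its seed.
* **Pixel sampling**: every vessel pixel plus an equal number of uniformly
  drawn background pixels per image (`class_balance = 1`). An optional
  `max_samples` cap takes a seeded subsample afterwards; repeated-training
  protocols in this package use caps of 100–150 thousand pixels, a size at
  which the fused accuracy is indistinguishable from the full sample on
  phantom sets while keeping repeated fits tractable.
* **Input normalization**: per-scale z-scoring with constants frozen into
  the model file — matched-filter magnitudes grow with kernel support, so
  unnormalized scales would enter the first layer on very different
  footings. `input_norm = FALSE` switches the deviation off.
* **Early stopping** is available (validation fraction + patience) but off
  by default; the default schedule is a fixed epoch count for exact
  reproducibility.
* **Architecture search** (`architecture_search()`) scores every hidden
  pair in $[1,10]^2$ by *training-set* pooled A~z~, which mirrors the
  original design procedure and is documented as overfit-prone by
  construction; ties break toward fewer total neurons, then a smaller
  first layer.

Serialized models round-trip bit-exactly through a JSON file holding the
architecture, weights, normalization constants, seed and training
configuration at 17 significant digits.

## Thresholding

Ten binarization methods operate on the detection response with vessels as
the high class. Global methods (Otsu, Ridler–Calvard, Kapur, Pal
exponential entropy, Tsai moments, histogram concavity) work on a 256-bin
histogram of the min–max rescaled response — the bin map is recorded so bin
thresholds convert back to response units — and break ties toward the
smallest threshold, making each a pure function of the histogram. RATS
thresholds in response units; Niblack, Sauvola and White–Rohrer compute
per-pixel thresholds from local means and standard deviations
(summed-area tables, reflect padding, window 15 by default, Niblack
$k=-0.2$, Sauvola $k=0.5, R=0.5$, White–Rohrer bias 1 — literature
defaults, all exposed).

Interpretation notes:

* The Pal–Pal entropy family has several variants; the exponential-entropy
  form $\sum_i p_{i|c}\, e^{1 - p_{i|c}}$ is implemented so the method is
  genuinely distinct from Kapur's Shannon form.
* Sauvola's verbal description ("raises the threshold where spread is
  low") conflicts with the standard published formula, which lowers it;
  the standard formula is implemented.
* Degenerate (constant) responses yield an all-background mask with a
  warning rather than an error, and a histogram with no concavity makes
  the concavity method fall back to Otsu with a warning.

## Evaluation

Gray-scale detections are scored by the area under the ROC curve,
$A_z$: `roc()` sweeps evenly spaced cutoffs (256 by default) over the
response range and `auc()` integrates by the trapezoidal rule (a literal
left Riemann sum is available and biases $A_z$ down). Dataset-level
$A_z$ pools all pixels of all images by default; per-image averaging is a
flag. Binary masks are scored by accuracy,
$(TP + TN)/(TP + FP + TN + FN)$, with vessels as the positive class.

## The phantom generator

Clinical angiogram sets with expert outlines are rarely shareable, so the
package generates phantoms with pixel-exact ground truth: smooth random
Bézier centerlines crossing the frame, a width $\sigma_v$ per vessel drawn
from `width_range`, dark Gaussian cross-sections of exact perpendicular
distance subtracted from a bright background, a smooth illumination field
(two random low-frequency sinusoids), and i.i.d. Gaussian noise. The
ground-truth mask is exactly the within-$2\sigma_v$ tube (≈95% of the
profile mass); `sigma_map` records the true width per mask pixel.

Default conditions — size 300, 5 vessels, widths 1.5–2.5, contrast 0.4,
illumination amplitude 0.1, noise 0.02, background 0.8 — are chosen to
emulate the moderate-noise, unevenly illuminated 300 × 300 angiograms the
method targets; "clean" test conditions switch noise *and* illumination
off. What the phantoms do **not** model: bifurcating trees, stenoses,
catheter and rib shadows, contrast-agent gradients along a vessel, and
correlated (quantum) noise. Passing phantom checks therefore demonstrates
correctness and the multiscale mechanism, not clinical performance.

## Numerical behaviour worth knowing

* Mean-subtracted matched kernels are only *bluntly* scale-selective: the
  response magnitude grows with kernel support, so the best-responding
  scale for a thin vessel sits above its true width (measured argmax 1.8
  for a true 1.5 on the 1.5–2.5 grid). The preferred scale still increases
  with true width — this is precisely why a learned fusion outperforms
  picking one scale.
* Otsu's objective is nearly flat across an empty histogram valley; with
  well-separated narrow modes the exact argmax is sampling-noise-driven
  anywhere in the valley. This is a property of the criterion, not a bug.
* $A_z$ from an evenly spaced threshold sweep is exactly invariant to
  affine response rescaling (the sweep range absorbs it) but only
  discretization-invariant (~$10^{-5}$ at 4096 cutoffs) under strongly
  non-linear monotone transforms.

## Problem sizes used by the checks

The package's property checks run at deliberately chosen sizes: filter
algebra on 16–40 px images against brute-force oracles; thresholding on
hundreds of random histograms against exhaustive scans; the fusion study
on 40 default phantoms (20 train / 20 test), training capped at 150k
pixels, with a 10-seed retraining stability protocol at 100k; end-to-end
reproducibility on 128 px phantoms. `scripts/acceptance.R` re-runs the
40-phantom study from scratch at a caller-chosen seed.

## Known limitations

* No vessel branching in phantoms; no Hessian/vesselness or morphological
  comparison detectors; no multi-level thresholding or graph-based
  refinement; no GPU or convolutional models.
* The architecture search trains one model per cell with a shared seed;
  its table is a point estimate, not a distribution.
* `alrawi`, `gmf_evol` and `gmf_entropy` presets are documented
  approximations of methods whose final tuned parameters are not public.
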