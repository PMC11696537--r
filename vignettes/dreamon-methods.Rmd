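---
title: "Class-interpolating GAN augmentation and noise-robustness benchmarking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-interpolating GAN augmentation and noise-robustness benchmarking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamon)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic data does and does not emulate, and the numerical
and design choices made where the design was genuinely open.

## The problem

A classifier trained on clean breast-ultrasound images and tested on noisy
ones faces a distribution shift, and its accuracy can collapse long before a
human reader's does. The package operationalizes this as a benchmark: train
a three-class lesion classifier (normal / benign / malignant) under
different augmentation strategies, then measure balanced accuracy and
calibration on test sets corrupted by parametric noise of increasing
severity.

## DreamOn: class interpolation through a dual GAN

The augmentation at the package's core mimics how REM dreams recombine
episodic memories. Two GANs are trained separately on single-class data and
combined only at synthesis time:

* `G_m`, an unconditional generator trained on the binary lesion masks
  alone. Blank masks are legitimate training samples — they are what the
  normal class looks like — so the mask prior covers all three classes.
* `G_s(mask, w, z)`, a conditional generator receiving a mask, a 3-class
  weight vector `w`, and a 400-dimensional standard-normal noise vector
  `z`. During training `w` is always one-hot; the discriminator sees
  (image, mask, class vector) triples.

After training, `w` is replaced by an *interpolated* vector with exactly two
strictly positive entries summing to 1, e.g. (0, 0.2, 0.8) — 20% benign,
80% malignant — and the synthesized image inherits `w` as its ground-truth
soft label. These samples sit near decision boundaries by construction. The
DreamOff control runs the identical pipeline with one-hot inputs, so any
benefit specific to DreamOn can be attributed to interpolation rather than
to the mere addition of GAN imagery.

### The weight sampler and mean matching

Because the classes are imbalanced (17% / 56% / 27%), assigning uniformly
random weights would over-represent minority classes relative to every other
training strategy. The sampler therefore enforces a *mean-matching*
constraint: across the generated dataset, the average weight of class `c`
must equal its true proportion `pi_c`.

The mechanism (the constraint itself leaves the mechanism open) picks one of
the three unordered class pairs uniformly, then draws the first class's
weight from a Beta distribution with pair-conditional mean `mu`. Uniform
pair choice makes the constraint a linear system,
`E[w_c] = sum over pairs containing c of mu(pair, c) / 3 = pi_c`,
with one degree of freedom; it is fixed symmetrically by requiring the mean
weight of "normal" to be the same in both pairs that contain it. For
(0.17, 0.56, 0.27) this yields

```{r}
weight_pair_means(c(0.17, 0.56, 0.27))
```

i.e. the benign–malignant pair is drawn with a strongly benign-leaning mean,
exactly compensating the benign mass the normal-containing pairs cannot
supply. The Beta concentration is `kappa = 2` (shapes `kappa*mu`,
`kappa*(1-mu)`): diffuse enough to cover the whole interpolation range,
informative enough that dataset means converge quickly. Draws are clamped to
`(1e-3, 1 - 1e-3)` so "two non-zero weights" stays literally true in
floating point.

A generated set is accepted when every class mean is within 0.02 of target
(re-drawing the weight list up to 10 times before any image is rendered).
The 0.02 band is calibrated to `n = 600` sets, where the standard error of a
class mean is about 0.01; `run_experiment()` scales the band by
`sqrt(600/n)` for smaller sets so the acceptance keeps the same z-score
meaning.

### Network architecture

All networks — both GAN pairs and the classifier — are compact
fully-connected residual/dense networks in base R with hand-derived
backpropagation and Adam, sized for 16–64 px grayscale images. This is a
deliberate design for a CPU-scale research tool: at these resolutions dense
layers train reliably in seconds-to-minutes, are bit-for-bit reproducible on
one CPU from a single seed, and keep every gradient checkable against
numerical differentiation (the test suite does exactly that). The classifier
keeps the residual-stage structure that Manifold Mixup requires — an input
embedding followed by residual stages `h <- h + W2 relu(W1 h + b1) + b2` —
so the enumerable mixing points (raw input, and each stage output) are
well-defined. `arch_scale = "full"` instantiates 4 stages of 2 blocks
(18 weight layers, width 256); `"tiny"`, used throughout the tests, 2
stages of 1 block at width 32. The GANs use the non-saturating loss on
discriminator logits with Adam betas (0.5, 0.999), the standard GAN
setting. Checkerboard-style generator artifacts are tolerated, not
corrected: they are shared by the DreamOff control, so they cancel out of
the comparison of interest.

## Comparison augmentations

* **SDA**: rotation `U(-15°, +15°)` about the image centre with zero
  padding (bilinear resampling via EBImage), horizontal flip with
  probability 0.5, then multiplicative brightness and mean-anchored
  contrast jitter. The ±20% jitter bounds are a package choice (mild,
  device-variation-like); rotation range and the *absence of vertical
  flips* are part of the protocol — ultrasound fields of view widen with
  depth, so a vertical flip is anatomically impossible.
* **Pixel-space Mixup**: `lambda*x + (1-lambda)*y` on pixels and labels,
  `lambda ~ Beta(0.8, 0.8)`, partners drawn across classes. The mixed set
  is materialized once as a fixed 600-image augmented set; Manifold Mixup,
  by contrast, mixes *on-line* during training with the model's current
  weights, choosing the mixing point uniformly among the raw input and the
  residual-stage outputs. This frozen-vs-on-line asymmetry mirrors the
  dataset-vs-training-procedure framing of the two methods.
* **Composition rule**: every non-vanilla strategy trains on the originals
  plus a same-size augmented set (600 + 600 = 1,200 at reference scale), so
  differences between strategies cannot be explained by training-set size.

## The noise ladders

Three families represent canonical ultrasound degradations: additive
Gaussian (electronics), multiplicative speckle `x + x*eps` (coherent
imaging), and salt & pepper (impulse/transmission). Level 0 is clean and
the intensity doubles per level, `sigma_k = sigma_1 * 2^(k-1)`, `k = 1..6`
— seven test conditions per family. Default base intensities (Gaussian
0.02, speckle 0.05, salt & pepper density 0.005) make level 6 severely
degraded; the principled route is `calibrate_base_intensity()`, which
bisects the base until a reference model's balanced accuracy at level 6
falls inside a chance band around 1/3 (up to 20 iterations or an intensity
tolerance of 1e-3). The calibration accepts a single reference model;
whether one model or a model pool defines "chance" is left to the user.
Salt & pepper splits corrupted pixels 50/50 between 0 and 1, and speckle
uses Gaussian multiplicative noise — both standard conventions where the
protocol does not pin down a distribution.

## Metrics and statistics

* **Balanced accuracy**: mean per-class recall under argmax; immune to the
  56% benign majority.
* **ECE**: confidence = max predicted probability; 10 equal-width
  right-closed bins; `sum_b (|b|/N) |acc_b - conf_b|`; empty bins
  contribute zero. Bin count and scheme are the dominant convention.
* **Stability Δ**: max − min of per-level median balanced accuracies —
  lower is a flatter, more noise-stable model. Medians over 5 runs use the
  exact middle order statistic.
* **Above-chance threshold**: the smallest `k` with
  `P(Bin(n, 1/3) <= k) >= 0.95`, divided by `n`; at `n = 90` this is
  `37/90 ≈ 0.411`. Note a subtlety: the strict Clopper–Pearson (Beta
  quantile) upper bound for 30/90 observed successes is ≈ 0.42; the
  binomial-quantile convention is implemented because it is the one that
  reproduces the protocol's printed 0.411. The discrepancy is documented
  here rather than resolved.
* **Fleiss' κ**: fixed-rater-count nominal agreement,
  `(Pbar - Pe)/(1 - Pe)`, with the degenerate all-one-category case
  defined as 1 under perfect agreement. The rater benchmark itself
  (4 raters × 30 images × 7 levels = 840 forced-choice trials) is supported
  as protocol generation only; collecting psychophysical data is out of
  scope.

## The phantom generator

Real sonography cannot ship with the package, so the fixtures emulate the
*statistical structure* the pipeline assumes, not ultrasound physics:

* speckle-textured background — a slowly varying Gaussian-blurred field
  times fine-grained multiplicative noise (first-order speckle
  approximation; no beamforming or attenuation model);
* benign: a smooth, randomly oriented hypoechoic ellipse; malignant: an
  irregular radial polygon with random harmonics and a posterior shadow
  column — the two canonical B-mode cues; normal: background only, blank
  mask;
* one-hot labels; largest-remainder class counts (780 at 0.17/0.56/0.27
  gives exactly 133/437/210); stratified train/test/val splits that hold
  class proportions constant, with a repair pass that reconciles per-class
  rounding against exact split totals.

Consequently, passing tests show that the *pipeline* behaves as specified —
labels are conserved, compositions are exact, classifiers learn a learnable
signal and degrade under noise — not that any accuracy level transfers to
real ultrasound. Phantom lesions are far easier than real ones, there is no
patient-level variance, and GAN image quality at 16–32 px is not assessed
(no FID or similar; image-quality scoring is a non-goal).

## Problem sizes and reproducibility

Default demo/test scales are the package's choice of desk scale: 16 px
phantoms for GAN-backed unit tests, 32 px with 240 phantoms, 40 epochs and
one run for the end-to-end demonstration — the smallest sizes at which the
tiny classifier reliably clears the above-chance threshold on clean images
so that degradation under noise is measurable rather than drowned in
small-sample noise. The reference protocol values (100 epochs, batch 20,
five runs, 600/90/90 splits at n = 780) are the configured defaults of
`train_config()` and the split logic.

Every stochastic stage derives its seed from a master seed via
`derive_seed(master, stage, indices...)` (a 32-bit multiplicative hash), and
all internal draws run under `with_seed()`, which restores the caller's RNG
state. Re-running any stage — phantom generation, GAN training, synthesis,
classifier training, the full experiment — with the same configuration and
master seed reproduces its output bit-for-bit on one CPU.

## Degenerate inputs and numerical choices

* Labels are validated onto the simplex at 1e-6; weight clamping keeps
  2-sparsity exact under floating point.
* Cross-entropy uses `log(pmax(p, 1e-12))`; discriminator losses use
  `softplus` on logits (never `log(sigmoid)`), so GAN losses cannot
  overflow. Non-finite losses abort with a diagnostic rather than train on.
* Validation checkpoint ties break to the earliest epoch; balanced-accuracy
  argmax ties break to the first (lowest-index) class, deterministically.
* `calibrate_base_intensity` assumes accuracy is non-increasing in
  intensity; a constant (input-ignoring) model is already at chance and
  returns the lower search bound.
* Images are stored in `[0,1]`; every noise family and augmentation clips
  back to `[0,1]`; 8-bit PNG round-trips quantize pixels to 1/255 (the RDS
  option is lossless).

## Known limitations

* Dense networks, not convolutional ones: adequate and fully reproducible
  at desk scale, but not a statement about ResNet-scale behaviour on real
  images.
* Mask synthesis is unconditional; only the class vector is interpolated.
  Whether the mask latent should itself be interpolated per class mixture
  is left open deliberately.
* Noise is synthetic and parametric; real scanner-to-scanner shifts are
  richer than any of the three families.
* The Mixup set is frozen once rather than re-sampled each epoch; the
  alternative is a one-line change but alters the comparison's framing.
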