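---
title: "lesiongan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lesiongan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the adversarial
model and its assumptions, the preprocessing operations and their exact
numerical conventions, what the synthetic-data generator does and does not
emulate, and the choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. The adversarial model

A generator $G(z; W_g)$ maps latent noise $z \sim \mathcal N(0, I_{100})$
to a $64\times64\times3$ image; a discriminator $D(x; W_d)$ estimates the
probability that $x$ is real. They play the minimax game

$$\min_G \max_D V(G, D) =
  \mathbb E_{x\sim p_{data}}[\log D(x)] +
  \mathbb E_{z\sim p_z}[\log(1 - D(G(z)))],$$

whose inner maximization has the closed-form solution
$D^*(x) = p_{data}(x)/(p_{data}(x)+p_g(x))$ and whose equilibrium has
$p_g = p_{data}$ with $D^* \equiv 1/2$ and value $-2\log 2$.
`optimalDiscriminator()` and `valueFunction()` expose this analysis on
discrete distributions, where it can be verified by brute-force grid
search; the test suite does exactly that, and also uses the $1/2$
equilibrium as the behavioral check on a degenerate training task
(section 5).

**Networks.** Both networks have five convolutional stages. The generator
uses fractional-stride (transposed) $4\times4$ convolutions
$z \to 4^2{\times}512 \to 8^2{\times}256 \to 16^2{\times}128 \to
32^2{\times}64 \to 64^2{\times}3$, batch normalization and ReLU on hidden
stages, Tanh output. The discriminator mirrors it with stride-2
convolutions and LeakyReLU (slope $0.2$), batch normalization on all but
the first stage, and a final $4\times4$ valid convolution producing the
head. The sources behind the architecture give the strides and stage
shapes but not the kernel size; $4\times4$, stride 2, padding 1 is the
standard DCGAN geometry consistent with those shapes, and the first
generator stage maps the latent vector to $4\times4\times512$ by a
stride-1, no-padding transposed convolution. One stated depth is ambiguous
("five convolutional layers" vs. "four convolutional neural networks"); we
resolve it as four strided stages plus one convolutional classifier stage —
five layers in total.

**Semi-supervised head.** With $N = 2$ real classes the head has $N+1 = 3$
softmax units $\{$benign, malignant, fake$\}$. We define
$p_{real}(x) = 1 - p_{fake}(x)$ identically, and class prediction
renormalizes the two real-class units. Three gradient sources meet at the
head: real images minimize $-\log p_{real}$, generated images minimize
$-\log p_{fake}$, and the labeled subset adds standard cross-entropy
toward the true class (the printed form of the supervised loss in the
source material is garbled; its own text says "standard cross-entropy",
which is what `supervisedLoss()` implements). The discriminator loss
decomposes as $D_{loss} = D_{real\,loss} + D_{fake\,loss}$, an identity the
trace reproduces at every iteration to $10^{-9}$.

**Training.** SGDM — classical momentum $v \leftarrow \mu v - \eta g$,
$w \leftarrow w + v$ — with the published defaults $\eta = 0.01$,
$\mu = 0.5$, batch 64, weights initialized $\mathcal N(0, 0.02^2)$, biases
zero. (One passage says "0.02% standard deviation", another "0.02"; 0.02
is adopted.) Per minibatch the discriminator takes one combined step
(adversarial real + fake + supervised terms, single SGDM update), then the
generator takes one step against the frozen discriminator; the ordering
within the combined step is not specified by the source and is fixed here
as a single summed gradient. The fake batch drawn for the discriminator
step is reused for the generator step (the generator has not changed in
between, so its forward caches remain valid; the discriminator has, so its
forward pass is redone). The generator objective defaults to the
saturating form $\mathbb E[\log(1 - D(G(z)))]$ stated by the source, with
the standard nonsaturating alternative $-\mathbb E[\log D(G(z))]$
available as `generatorLossForm = "nonsaturating"` for practical training.
All probabilities entering logarithms are clamped at $\varepsilon = 10^{-7}$.

**Batch normalization.** Per-channel over $(H, W, N)$, $\epsilon = 10^{-5}$,
training mode uses batch statistics and maintains running statistics
(momentum 0.1) that inference (prediction, generation) uses, so a saved
model is deterministic per image. Running statistics advance on real
batches only, so generated batches do not contaminate the inference
statistics.

## 2. Preprocessing conventions

Pipeline order: bicubic rescale → normalize to $[0,1]$ → histogram
equalization → combined USM + GHPF sharpening → CIELAB color balance →
median filter. Every stage after rescaling can be toggled. Numerical
conventions, fixed so the oracle tests are exact:

* **Bicubic**: Keys cubic-convolution kernel with $a = -0.5$ (the standard
  kernel consistent with a 16-neighbor weighted average), pixel-center
  coordinate mapping, edge replication, final clip to the declared range.
* **Quantization/rounding**: half-up (`floor(x + 0.5)`) everywhere an
  intensity is quantized to 256 levels; R's default round-half-even would
  shift the equalization oracle values.
* **Histogram equalization**: classical CDF remap
  $\mathrm{round}\big((cdf(v)-cdf_{min})/(1-cdf_{min})\cdot 255\big)$.
  Color images are equalized on the CIELAB lightness channel with chroma
  preserved — the source equalizes without naming a channel strategy, and
  equalizing RGB channels independently distorts hue, which matters for
  lesion color. A constant image is returned unchanged (the remap is 0/0
  there).
* **Sharpening**: USM is spatial (`img + amount·(img − blur)`; Gaussian
  kernel truncated at $4\sigma$, reflect padding); GHPF is frequency-domain
  with transfer $H(u,v) = 1 - e^{-D^2/(2 D_0^2)}$, $D$ in cycles/pixel.
  The source names the two sharpeners and their combination ("added and
  multiplied by the weight factor") but gives no formulas or weights;
  defaults are $\sigma = 1$, amount 1, $D_0 = 0.05$ (one tenth of
  Nyquist), gain 1, weights $0.5/0.5$, all configurable.
* **CIELAB color balance**: per-channel standardization to target
  means/stds; a zero-variance channel keeps scale factor 1. The reference
  statistics are never stated by the source; the package defaults
  ($\mu = (50, 0, 0)$, $\sigma = (25, 10, 10)$ LAB units) center images on
  neutral mid-lightness and are documented as invented defaults.
  Conversions use `grDevices::convertColor` (sRGB D65).
* **Noise models**: seeded; salt-and-pepper flips whole pixel locations to
  the range endpoints equiprobably, Gaussian noise is scaled to the
  declared range, Poisson resampling uses a configurable photon budget
  (default 255 — the source does not parameterize it).
* **Median filter**: $k\times k$ sliding median, reflect padding. One
  source sentence ("the median filter was implemented using Gaussian
  noise") is ambiguous; we read it as "the median filter was selected
  because it best removes Gaussian noise", consistent with that source's
  own noise-comparison table, so the pipeline never injects noise.

MSE, PSNR ($10\log_{10}(MAX^2/\mathrm{MSE})$, $\infty$ at MSE 0) and SSIM
(11×11 Gaussian window, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, valid
window positions, Rec. 601 luminance for color inputs) quantify the
stages. The source's printed MSE/PSNR/SSIM tables are mutually
inconsistent under the standard PSNR formula for any MAX, so they are not
used as oracles anywhere; the metrics are verified against closed forms
and brute-force reimplementation instead.

## 3. The synthetic-data generator

The generator emulates the ISIC archive layout: PNG images plus a
`metadata.csv` with exactly
`image_name,patient_id,sex,approx_age,anatomical_site,diagnosis,benign_malignant,target`,
missing fields as empty strings, `target == 1` iff malignant. Each image
is a skin-toned background (tan base, gentle illumination gradient, fine
grain) with one lesion blob whose polar radius is an ellipse modulated by
a random 5-term Fourier series scaled by the class irregularity, filled
with the class color plus smooth-and-white variegation noise at the class
color spread, and optional dark hair-like streaks. Class signal is carried
by border irregularity and color statistics, echoing the clinical lesion
criteria (symmetry, color, size, form).

Defaults are the stated world: 2000 images, balance 0.5 (one passage says
2000 total, another 2000 per class; the smaller reading is the default and
neither is treated as normative — everything is configurable), side 64,
hair probability 0.2, benign irregularity 0.06 vs malignant 0.25, benign
color spread 0.03 vs malignant 0.09 per channel, benign mean RGB
(0.70, 0.52, 0.42) vs malignant (0.24, 0.12, 0.10). The color means are
chosen widely separated so that a trivial per-image mean-color threshold
reaches ≥ 95% accuracy — this is a stated invariant of the fixture world,
and it guarantees the downstream classifier tests are well-posed: a green
classifier test establishes that the semi-supervised machinery learns an
easy signal, *not* that it would reach the published accuracy on real
dermoscopy. The generator makes no attempt at photorealism: no dermoscopy
optics, no pigment network textures, no multi-site variation, no class
overlap. Everything is deterministic given `SyntheticParams` (per-image
child seeds derive from the dataset seed).

The 70/30 split takes `round(0.7·n)` training records, allocated across
classes by largest remainder, so each class's test share matches the
global 30% as closely as integers allow (the per-class-rounding
alternative would give 8/2 instead of the documented 7/3 on a 5+5
example). The unlabeled 30% is then drawn per class within the training
set — the source does not say whether the unlabeled fraction is
stratified; drawing it per class keeps the supervised subset balanced.

## 4. Scaled-down training properties

The published headline numbers (99.38% accuracy after long training on
ISIC 2017) are not reproducible at desk scale; the acceptance suite
substitutes two properties computed end to end by the package:

* **Recovery**: on 400 synthetic images (70/30 split, 30% unlabeled,
  batch 16, 3 epochs, default lr 0.01/momentum 0.5, seed fixed), test
  accuracy must reach ≥ 90%. Three epochs is 51 iterations — enough for
  the color signal, and comfortably inside the time budget.
* **Equilibrium**: on 64 identical constant images (a distribution the
  generator can represent exactly — its near-zero-initialized Tanh output
  starts at the data value), the mean discriminator score over the final
  20% of iterations of an 8-epoch run must lie in (0.3, 0.7). With the
  default saturating loss at lr 0.01 the score oscillates between the two
  saturated regimes with a stable mean near 0.43 (reproducible across
  seeds); the oscillation is the classic sign of an over-aggressive
  learning rate on a degenerate task, and the criterion is met by the
  time-averaged score, which is also what the published score curves plot
  per iteration.

## 5. Numerical and degenerate-input choices

* Tanh outputs are clamped to $\pm(1 - 10^{-7})$ so the "strictly inside
  $(-1,1)$" contract survives double-precision saturation.
* Probability logarithms are $\varepsilon$-clamped ($10^{-7}$);
  `supervisedLoss` reports (via a message) when a true-class probability
  was clamped.
* Zero-denominator classification metrics report 0 and a flag rather than
  raising, keeping batch evaluation total; BAS is always
  $(recall + specificity)/2$ of the reported values.
* ROC ties: threshold sweep over unique scores; diagonal segments make the
  trapezoidal AUC equal the pairwise statistic with ties counted ½.
* Predicted label is malignant exactly when the renormalized malignant
  posterior is ≥ 0.5, so labels and scores are threshold-consistent
  including the boundary.
* The checkpoint container is an RDS file holding both networks, the
  `TrainConfig` and the RNG state; the trace CSV has one row per
  iteration with the score and loss columns.

## 6. Known limitations

* Training at realistic scale is slow: the conv/transposed-conv kernels
  are single-threaded C++ GEMMs, about 3–5 s per batch-16 iteration on one
  CPU. The package is built for desk-scale verification, not for
  reproducing long runs.
* The synthetic world is easy by construction (see section 3); results on
  it bound nothing about real dermoscopy performance.
* `readPng` supports the 8-bit non-interlaced subset of PNG the package
  itself writes (gray/RGB/RGBA); exotic PNGs from other tools may be
  rejected.
* No hair-removal inpainting; the median filter is the only mitigation of
  streak artifacts, mirroring the source pipeline.
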