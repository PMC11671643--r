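---
title: "Single-step diffusion sampling for reconstruction-based anomaly segmentation"
author: "diffAnomaly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step diffusion sampling for reconstruction-based anomaly segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffAnomaly)
```

## The model

diffAnomaly implements unsupervised, reconstruction-based anomaly
segmentation of grayscale medical images with a denoising diffusion
probabilistic model (DDPM). The idea: train a noise predictor only on
*healthy* images of a single class (e.g. skull-stripped axial brain MRI
slices), then ask it to reconstruct an unseen, possibly anomalous image.
The model can only reproduce what it has learned — healthy anatomy — so
anomalous regions come back "repaired", and the pixel-wise squared
difference between input and reconstruction marks the anomaly.

The forward (corruption) process is fixed. With a linear variance schedule
$\beta_t \in (0,1)$, $t = 1,\dots,T$, $\alpha_t = 1-\beta_t$ and
$\bar\alpha_t = \prod_{s\le t}\alpha_s$, the closed-form marginal lets us
jump from a clean image $x_0$ to any timestep in one step:

$$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon .$$

The defaults are the standard DDPM setting: $T = 1000$, $\beta$ linear from
$10^{-4}$ to $0.02$, under which $\bar\alpha_T \approx 4\times10^{-5}$
(the signal is essentially destroyed at the end of the chain).

A UNet-style network $\epsilon_\theta(x_t, t)$ is trained to predict the
noise with the plain L2 objective
$L = \lVert \epsilon - \epsilon_\theta(x_t,t) \rVert^2$, with $t$ drawn
uniformly from $\{1..T\}$ and a fresh noise field per step.

**Reconstruction.** Two samplers are provided:

* *Iterative (classical DDPM)*: repeatedly apply
  $x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\big(x_t -
  \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\epsilon_\theta(x_t,t)\big) +
  \sigma_t z$, which costs $\lambda$ network evaluations from timestep
  $\lambda$.
* *Single-step*: algebraically invert the closed-form forward equation with
  the one noise prediction at $\lambda$:
  $\hat x_0 = (x_\lambda - \sqrt{1-\bar\alpha_\lambda}\,
  \epsilon_\theta(x_\lambda,\lambda))/\sqrt{\bar\alpha_\lambda}$ — one
  evaluation, i.e. O(1) instead of O($\lambda$) sampling cost. The package
  asserts this contract as *evaluation counts* (a hardware-free statement),
  never as wall-clock time.

Anomaly detection uses *partial* diffusion: the input is noised only to an
intermediate $\lambda$ (default 300, recommended window 250–400 of
$T=1000$) so its global structure survives and the reconstruction stays
faithful to the individual anatomy while healing what the healthy-trained
model cannot explain.

## Simplex-noise corruption

The corruption $\epsilon$ is multi-octave 2D simplex noise rather than
white Gaussian noise. Octave $k$ ($k = 0..N-1$) is simplex noise at
frequency $\nu\,2^k$ with amplitude $\gamma^k$; defaults $\nu = 2^{-6}$
cycles/pixel, $N = 6$, $\gamma = 0.8$. Summing octaves moves the value
distribution toward Gaussian (as the diffusion equations assume) while
keeping power concentrated at low spatial frequencies, so the corruption —
and therefore what the denoiser learns to remove and replace — is
*structured and anomaly-sized* rather than per-pixel speckle. The package
verifies this spectrally: the mean power of simplex fields below $2\nu$
exceeds that of equal-variance Gaussian fields by two orders of magnitude.

Two choices the octave construction leaves open were fixed as follows:

* **Standardization.** Each sampled field is affinely standardized to
  exactly zero mean and unit variance, since the forward equation assumes a
  unit-variance $\epsilon$.
* **Frequency unit.** $\nu$ is interpreted as cycles per pixel, so
  $\nu = 2^{-6}$ gives a 64-pixel characteristic scale on a 256-pixel
  image (and a full-image-scale structure on the 64-pixel phantoms).
* **Per-sample randomness.** The simplex lattice is deterministic given its
  permutation table; fresh fields are obtained by seeding the table and by
  translating each octave's lattice by a seeded random offset. Every field
  is a pure function of its `SimplexSpec`, and training derives a child
  seed per iteration from the run seed.

## The noise predictor

The network follows the standard DDPM UNet: residual blocks
(group norm → SiLU → 3×3 conv, twice) with the sinusoidal timestep
embedding linearly projected into every block, self-attention at configured
spatial resolutions plus one attention block at the bottleneck,
stride-2 convolutional downsampling, nearest-neighbour upsampling, skip
connections concatenated at equal resolutions, and a zero-initialized
output convolution. Attention placement follows the usual ordering
(after the residual blocks of a level); timestep conditioning is an
additive per-channel shift (plain group normalization, not AdaGN).

Because no automatic-differentiation framework is available in this stack,
the network and its gradients are implemented in the package: convolutions
as im2col + GEMM in C++ (RcppArmadillo), group norm / attention / SiLU in
R with hand-derived backward passes. The test suite validates every
gradient against central finite differences.

Two configurations ship as YAML profiles:

| setting | `full` profile | `mini` profile |
|---|---|---|
| image size | 256 | 64 |
| base channels | 128 | 16 |
| channel multipliers | 1,1,2,3,4 | 1,2,2 |
| res blocks / level | 2 | 1 |
| attention at | 32, 16 px | 16 px |
| attention heads | 2 | 1 |
| iterations | 100&nbsp;000 | 2&nbsp;000 |
| learning rate | 1e-4 | 3e-4 |
| EMA decay | 0.9999 | 0.995 |

The `full` profile carries the full-scale reference hyperparameters
(AdamW with betas 0.9/0.999, weight decay 0, batch size 1, dropout 0, L2
loss without SNR reweighting, uniform $t$ sampling). The `mini` profile is
this package's desk-scale counterpart, chosen once as follows: the
architecture is the same family shrunk to 64×64 with attention kept at the
(proportionally lowest) 16-pixel levels; the learning rate is raised to
3e-4, a conventional value for networks this small, so 2 000 batch-1 steps
suffice; and the EMA decay is shortened to 0.995 because an 0.9999 average
has an effective horizon of ~10 000 steps and would still be dominated by
the initialization after 2 000 — inference always uses the EMA parameters,
so the EMA horizon must fit inside the run length. $T$ stays 1000 so
$\lambda = 300$ keeps its meaning.

## Segmentation pipeline

`segmentSingle()` composes: unit→symmetric range conversion → forward
diffusion to $\lambda$ with a fresh simplex field → one noise prediction →
closed-form inversion → clip to $[-1,1]$ → symmetric→unit conversion →
error map $E_{sq} = (x_0-\hat x_0)^2$ → threshold $E_{sq} > \tau$ →
postprocessing. Postprocessing is a 3×3 binary dilation followed by
retention of the largest 8-connected components (defaults: keep 1
component, minimum area 5 px) — squared-error maps produce scattered
false-positive specks that these two standard operations remove.

Numerical and convention choices:

* **Intensity scale of $\tau$.** $\tau$ applies to squared errors of
  *unit-range* images; $\tau = 0.3$ therefore corresponds to an absolute
  intensity difference of $\sqrt{0.3}\approx 0.55$. The conversion between
  unit and symmetric ranges is owned by one module so this semantics is
  unambiguous, and $\tau$ is configurable everywhere. In the desk-scale
  experiments $\tau$ is tuned on a small labelled validation split
  (`tuneThreshold()`), because the healthy-tissue reconstruction error of a
  briefly trained mini model sits on a different scale than a fully trained
  one.
* **Reverse-process variance.** $\sigma_t^2 = \beta_t$, the simpler of the
  two fixed-variance conventions; the stochastic term is dropped at $t=1$
  and in deterministic mode.
* **Clipping.** $\hat x_0$ is clipped into $[-1,1]$ before the error map
  (`clip = FALSE` retains the raw inversion for diagnostics).
* **$\lambda$ policy.** Fixed $\lambda = 300$ by default; a seeded uniform
  draw from the 250–400 window is available (`randomLambda = TRUE`).
* **Error-map space.** $E_{sq}$ is computed against the contrast-stretched
  slice (the network's input space), not the raw scanner intensities.
* **Ensemble.** `ensembleSegment()` runs the single-step segmenter at
  several timesteps (default 250/300/350/400, fresh corruption each),
  counts per-pixel votes over the *pre-postprocessing* masks, keeps pixels
  with at least `minVotes` detections (default: majority,
  $\lceil M/2\rceil$), then postprocesses once.

Metrics are Dice, IoU, precision, recall on masks and pixel-wise ROC AUC
(Mann–Whitney with midranks) on the raw error map. Degenerate conventions:
two empty masks score 1 everywhere (perfect agreement); an empty prediction
against non-empty truth scores 0. Aggregation reports mean ± population
standard deviation, with a helper that picks four equidistant slices from
an annotated range for per-volume evaluation.

## Synthetic phantoms: what they emulate and what they do not

The phantom generator is the package's self-contained test surface. A
healthy phantom is a soft-edged ellipse (base intensity 0.5) with
low-amplitude smooth cosine texture (±0.05), per-sample jitter in axes,
rotation, centre and texture, and an exactly-zero background — a
single-class population with consistent global structure, the regime the
method assumes. Anomalies are soft-rimmed disks (radius 4–8 px) with an
additive intensity offset (+0.4 by default), placed at seeded interior
locations; the ground-truth mask is exact by construction, and the offset
is a calibrated difficulty dial down to 0. Base intensity and texture
amplitude were chosen so the default offset keeps every pixel inside
[0, 1], which the `PhantomSpec` validity check enforces.

Passing tests on phantoms demonstrate that the machinery — corruption,
training, reconstruction, thresholding, metrics — behaves as specified and
that the end-to-end method recovers planted anomalies far above untrained
and random baselines. They do *not* demonstrate clinical performance:
phantoms have no MRI physics (no bias fields, no Rician noise, no partial
volume effects), far less anatomical variability than real brains, and
anomalies that are brighter-than-surroundings disks rather than
infiltrating lesions. Full-scale claims require the real NIfTI pipeline
(`loadVolume()`, `getSlice()`, `cacheDataset()`) with actual healthy and
anomalous MRI volumes and the `full` profile.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run entirely at desk scale,
chosen so a laptop CPU reproduces them in minutes: mini profile (64×64,
~208k parameters), 200 healthy training phantoms, 2 000 training
iterations, $\tau$ tuned on 10 validation phantoms, evaluation on 50
held-out anomalous phantoms at $\lambda = 300$, plus a contrast sweep at
offsets 0.4/0.2/0.0. Property checks (forward/inverse identity, oracle
reverse chain, noise spectra, metric brute-force agreement, monotonicity,
reproducibility) use small images and seconds of compute.

## Known limitations

* Batch size is fixed at 1 (the reference setting); there is no
  multi-image batching, GPU path, or mixed precision.
* Only the linear variance schedule is implemented; `cosine` is a
  recognized-but-rejected configuration name.
* The slice pipeline is strictly 2D; volumes are segmented slice-wise.
* Checkpoints are R serializations, not portable across frameworks.
* The iterative sampler exists for comparison and testing; at full scale
  it is two to three orders of magnitude more expensive than the
  single-step path, which is the package's point.
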