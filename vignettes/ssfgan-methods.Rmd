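---
title: "Spectro-spatial maps and GAN augmentation for auditory attention decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectro-spatial maps and GAN augmentation for auditory attention decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a multi-speaker scene, the direction a listener attends to (left or
right) modulates the scalp topography of EEG alpha power (8–13 Hz).
`ssfgan` decodes that direction from short decision windows of multichannel
EEG, and addresses the chronic scarcity of labeled EEG by augmenting the
training set with a class-conditional generative model. The pipeline is:

1. **Preprocessing** — zero-phase 4th-order Butterworth high-pass at
   0.5 Hz, polyphase resampling to 70 Hz, per-channel z-scoring per trial.
2. **Spectro-spatial feature (SSF) maps** — per decision window, the FFT
   band power of each electrode is interpolated over a 2-D projection of
   the montage onto a 28×28 mesh, giving one topographic image per window.
3. **AD-GAN** — an auxiliary-classifier GAN whose generator synthesizes
   labeled maps from a 100-dimensional latent vector, and whose
   discriminator carries a real/generated (source) head and a left/right
   (class) head that doubles as the attention classifier.
4. **Evaluation** — precision/recall/F/accuracy, generated-vs-real
   similarity (ED/PCC/K-LD), noise-robustness curves, traditional
   augmentation baselines, McNemar's exact test, intra-subject 5-fold
   cross-validation.

## Feature extraction in detail

**Windowing.** A window specification is a duration `T` and fractional
overlap. The window is `L = round(T * fs)` samples, the hop is
`round(L * (1 - overlap))`, and the count is `floor((n - L)/step) + 1`.
Training sets conventionally use 50% overlap; test sets use 0% so that no
two test decisions share samples (with 0.1 s windows and the 20% test share
of a 48-minute recording this reproduces the canonical 5,760 windows per
subject). The split into train/test happens at the *trial* level before
windowing; splitting windows directly would leak samples through overlap.

**Band power.** The one-sided FFT power spectrum is normalized by the
Parseval convention — per-bin powers, with interior bins doubled, sum to
the mean squared signal — and band power is the **sum** of per-bin powers
over bins with `low <= f_k <= high` (edges inclusive). A "mean over bins"
reading of band power would make the value depend on window length through
the bin count and would not satisfy the Parseval cover identity the tests
enforce (a unit-amplitude in-band sinusoid must carry its full `A^2/2`
power). Sum semantics keeps band powers comparable across window lengths.

**Projection.** Electrodes live on the unit head sphere (x nasion, y left
ear, z vertex). The azimuthal-equidistant projection about the vertex maps
each electrode to polar coordinates `(rho, theta)` with `rho` the arc
distance from the vertex — distances from the pole are preserved exactly,
which is the projection's defining property and one of the tested
invariants. The packaged 64-channel montage is a *synthetic idealized*
10-10-style layout built from sagittal and lateral arcs (the environment
carries no digitized electrode database); it is left/right symmetric,
which is all the simulation and mapping require.

**Interpolation.** Scattered per-electrode values are interpolated with a
reduced Hsieh–Clough–Tocher macro-element over a Delaunay triangulation
(both implemented in-package; no R package in the target environment
provides them). Each triangle is split at its centroid into three cubic
Bézier patches; corner values and gradients fix the boundary control net,
the requirement that the cross-boundary derivative vary linearly along
outer edges ("reduced" condition) fixes each patch's interior ordinate,
and C1 continuity across the internal edges yields the remaining control
points. Vertex gradients are estimated by inverse-distance-weighted least
squares over triangulation neighbors. Consequences, all tested: the
interpolant reproduces data points, constants and linear fields exactly;
given *exact* gradients the element reproduces quadratics to machine
precision (this pins the control-net algebra); the evaluation is linear in
the electrode values, so a dataset of maps is one matrix product. The
28×28 grid spans the square `[-r, r]^2` with `r` = 1.05 × the largest
projected radius; nodes outside the electrode convex hull take the fill
value 0 (applied before normalization).

**Normalization.** Each map is min–max scaled to `[-1, 1]`, matching the
generator's tanh output range; the affine parameters are stored in
`scale_info` so maps remain invertible to power units. The source material
does not state the image scaling; this is the package's choice.

## The AD-GAN

The architecture is fixed by its printed per-layer parameter counts, which
the builders reproduce exactly (and the tests assert):

* Generator: FC 100→12544 (1,266,944), BN (50,176), reshape 7×7×256,
  dropout, tconv 5×5 256→128 (819,328), BN+ReLU, 2× upsample, tconv 3×3
  128→64 (73,792), BN+ReLU, 2× upsample, tconv 3×3 64→32 (18,464), BN+ReLU,
  tconv 3×3 32→1 (289), tanh.
* Discriminator: conv 3×3 stride-2 chain 1→64→128→256 then stride-1
  256→512 (640 / 73,856 / 295,168 / 1,180,160), LeakyReLU(0.2) + dropout
  throughout, flatten to 8,192, source head FC→1 sigmoid (8,193), and the
  auxiliary class head FC→2 softmax reconstructed from the text (the
  printed table omits it).

Kernel sizes and the latent dimension are not printed anywhere; they are
the unique integer solutions of `k^2 * C_in * C_out + C_out = printed
count` (5×5 for the first transposed convolution, 3×3 elsewhere) and
`12544 * (d + 1) = 1,266,944` (d = 100). Stride-1 transposed convolutions
with 'same' padding are implemented as convolutions with swapped channel
roles — identical parameter count, shape and expressiveness.

**Conditioning.** The label enters the generator as an elementwise product
of the latent vector with a learned 100-dimensional class embedding;
concatenation would contradict the printed FC fan-in. The embedding is
initialized around 1 with spread 0.5: near-identity initializations give
the auxiliary head no early class signal to latch onto and stall
conditioning at the small training scales this package targets.

**Objectives.** With source probabilities `p` and class probabilities `q`,
the discriminator minimizes the negated log-likelihoods
`L_source = -(E log p(real|x_r) + E log(1 - p(real|x_g)))` plus
`L_class` summed over real and generated batches; the generator minimizes
`L_source - L_class` restricted to its own terms (equivalently maximizes
`L_class - L_source`). Probabilities are clamped at `1e-7`. Training
alternates full discriminator and generator Adam steps per minibatch
(lr 1e-4 / 2e-4, beta1 0.5, beta2 0.999, batch 8, the printed
best-performing row; the 32 mentioned elsewhere in the text is available
via the config). All randomness flows through R's RNG, so a seed fixes the
entire loss history bit-for-bit.

**Inference-time batch norm.** `generate_maps()` and training-mode
evaluation use batch statistics rather than moving averages: at a few
dozen epochs on hundreds of images, moving averages (momentum 0.9) still
lag the statistics the weights were trained against and produce visibly
miscalibrated samples. This is recorded here as a deliberate deviation
from framework defaults, appropriate at this scale.

The whole stack — im2col convolutions on BLAS, batch norm, Adam — is
implemented in base R because the target environment has no deep-learning
framework; every layer's backward pass is verified against central
differences in development and the training loop's freeze contract
(discriminator untouched during generator steps and vice versa) is
asserted by the tests through an instrumented optimizer.

## Synthetic data: the stated world

`simulate_recording()` builds each channel as unit-variance `1/f^beta`
background noise (spectrally shaped Gaussian noise via inverse FFT,
beta = 1 by default) plus an alpha sinusoid (10 Hz, random phase per
channel). On the hemisphere keyed to the label the amplitude is multiplied
by `lateralization`; `snr` is the alpha-to-background power ratio on the
unboosted side. Defaults — lateralization 3, snr 5, 70 Hz, 64 channels —
are the recovery-experiment conditions stated for this package's
acceptance. With lateralization 3 the hemispheric alpha *power* ratio is
~9 (amplitude squared), diluted only by the in-band share of the
background; the tests check this analytic oracle within 20%.

Which hemisphere's alpha rises for "left" attention is physiologically
contested; it is a config switch (`boost_side`, default `"ipsi"`), and all
recovery claims depend only on the mapping's consistency, not its sign.

What a green recovery test establishes: the full path (simulation →
preprocessing → band power → projection → interpolation → discriminator)
can recover a *strong, stationary, single-band* hemispheric asymmetry from
a few hundred maps. What it does not establish: performance on real EEG,
which is nonstationary, artifact-laden, and far weaker-signaled. Real
corpora are deliberately out of scope here.

## Evaluation choices

* **ED / PCC / K-LD** are nowhere defined operationally in the source
  material; this package uses per-class mean-image Euclidean distance
  (normalized by pixel count), per-class mean-image Pearson correlation
  ("PCC" is expanded oddly in the literature but used as a correlation
  with a 0.8 similarity threshold), and KL divergence between 64-bin
  pooled intensity histograms with `1e-8` smoothing. Because these are
  reconstructions, printed similarity values are *not* comparison targets.
* **Noise robustness** follows `n*X + m*randn` on the `[0, 255]` intensity
  scale with clipping; the reference formula's third dimension (a 3-channel
  image) is applied per actual channel count — SSF maps have one channel.
* **McNemar**: exact two-sided binomial below 25 discordant pairs,
  continuity-corrected chi-square above — the standard small-sample
  practice; the exact branch equals brute-force binomial summation in the
  tests.
* **Cross-validation** is stratified per subject so every fold carries
  both classes.

## Numerical and degenerate-input decisions

* Zero-variance channels z-score to zeros with a warning, not NaN.
* Classification ties break toward the first class ("left"), documented.
* Bowyer–Watson triangulation rejects collinear/duplicate electrode sets;
  interpolation requires at least 4 electrodes.
* `segment_windows` enforces `L <= n_samples`; a window equal to the
  recording yields exactly one window regardless of overlap.
* Arbitrary window lengths are supported, including 0.1 s, although the
  canonical set is {0.5, 1, 2, 5, 10} s — the source material uses both.
* Band edges are inclusive on both sides; an empty band (no bins) is an
  error rather than silently zero.

## Known limitations

* The montage is idealized, not digitized anatomy; absolute map geometry
  differs from vendor layouts, though symmetry and ordering are right.
* The GAN is CPU-scale: the reference regime (200 epochs on ~10^5 maps) is
  out of scope, and smoke-scale GANs are judged on stability and class
  separability, not sample realism.
* EDF support covers continuous equal-rate recordings only.
* HDF5 containers are replaced by a plain-text dataset directory (no R
  HDF5 bindings in the target environment); YAML configs by JSON.
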