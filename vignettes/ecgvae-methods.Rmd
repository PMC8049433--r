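---
title: "Methods: a variational autoencoder for single ECG cardiac cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a variational autoencoder for single ECG cardiac cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgvae)
```

## The problem

An electrocardiogram records the heart's electrical activity; one cardiac
cycle — P wave, QRS complex, T wave — carries most of the diagnostically
relevant morphology. `ecgvae` learns a compact, generative representation of
a single cycle: a probabilistic encoder maps a 400-sample (800 ms at 500 Hz)
R-peak-centered window to a 25-dimensional latent Gaussian, and a decoder
maps any 25-vector back to a cycle. Because the latent prior is standard
normal, decoding i.i.d. N(0, I) draws generates new, synthetic cycles; and
because the representation is low-dimensional, individual latent features
often align with recognizable morphology (wave amplitudes, ST level), which
can be inspected with single-feature traversals.

## Preprocessing

Cycle extraction anchors on R peaks and steps an equal distance forward and
backward: the half-open window `[p - 200, p + 200)` (0-based indices
throughout; all windows half-open). Peaks too close to a record edge are
dropped and counted, never an error. The half-width is configurable because
the approach applies to cycles of any duration, but 200 samples at 500 Hz is
the default that yields the canonical 400-sample vector.

R peaks can come from stored annotations (the tested reference path) or from
a built-in detector in the Pan-Tompkins tradition: 5–15 Hz Butterworth
band-pass, squared first difference, 150 ms moving-average energy, a
threshold at a configurable fraction of the maximum energy, and refinement
of each candidate to the local raw-signal maximum. The detector exists so
that unannotated records are usable; it only affects preprocessing, never
the model, and its accuracy target in the test suite (±5 samples on
simulated records) is deliberately modest. Segmentation of P/T boundaries is
out of scope — windowing uses only R peaks.

Training data is used in raw mV by default (`normalize = "none"`); per-cycle
and global z-scoring are offered for numerically difficult data, with
parameters returned so the transform inverts exactly. The package assumes
amplitudes are calibrated in mV and documents rather than verifies this.

## The model

Both halves of the autoencoder are dual-branch networks, so that local
features (convolutions) and whole-signal structure (dense layers) are
captured simultaneously:

* **Encoder.** A convolutional chain of four blocks — 1-D convolution
  ("same" padding, kernel 7), batch normalization, ReLU, ×2 max-pooling —
  with channel counts (8, 16, 32, 64), followed by one final convolution
  collapsing to a single channel: 400 samples → 25 values. In parallel, a
  dense chain 400 → 256 → 64 → 25 (each layer with batch norm and ReLU).
  The two 25-vectors are concatenated to 50, and two independent dense
  heads map them to the latent mean μ and log-variance log σ² (25 each).
* **Sampling.** The latent code is z = μ + σ ⊙ ε with ε ~ N(0, I) — the
  reparameterization that keeps sampling differentiable.
* **Decoder.** A dense chain 25 → 64 → 128 → 256 → 400 (four blocks with
  batch norm and ReLU) in parallel with a deconvolution chain that reshapes
  the 25-vector to 25 positions × 1 channel and applies four blocks of
  convolution, batch norm, ReLU and ×2 nearest-neighbour upsampling with
  channels (32, 16, 8, 1): 25 → 400. The two 400-vectors are concatenated
  to 800 and one final dense layer produces the reconstructed cycle.

The published description of this architecture fixes the branch outputs
(25), the concatenation widths (50 and 800), the block structure, and the
latent dimension; kernel size, channel counts and dense widths are open. The
defaults above were chosen once for mirror-symmetric capacity and are all
exposed in `model_config()`. Two constraints are enforced at configuration
time: `input_length` must be divisible by `pool_factor^4`, and — because the
deconvolution chain upsamples the latent vector ×2 four times — equal to
`latent_dim * pool_factor^4`. The defaults satisfy 400 = 25·2⁴, and the
scaled variant 160 = 10·2⁴ is exercised in the tests. Whether the two dense
heads share a hidden layer is not specified in the source description; they
are implemented as independent maps from the 50-vector.

## Losses and training

The loss combines the mean squared reconstruction error with the
Kullback–Leibler divergence of the encoder's diagonal Gaussian from the
standard-normal prior, which has the closed form

> KL(N(μ, diag σ²) ‖ N(0, I)) = ½ Σᵢ (μᵢ² + σᵢ² − log σᵢ² − 1).

The per-sample objective is `MSE + β · KL / input_length`. At the default
β = 1 this equals the natural unweighted objective — the *sum* of squared
errors plus KL — divided by the constant cycle length, so the two terms are
balanced exactly as in the unweighted formulation while remaining
scale-comparable across batch sizes. Weighting the KL sum against the
*mean* squared error instead (a factor-400 stronger KL pressure) collapses
the posterior on realistic amplitude scales: reconstructions degenerate
toward the mean cycle. β is exposed for the usual β-VAE trade-off, with an
optional linear warm-up (`kl_warmup_epochs`); β = 0 trains a plain
autoencoder.

Optimization is Adam (β₁ = 0.9, β₂ = 0.999) for 720 epochs by default,
matching the published protocol; batch size (64), learning rate and β are
package conventions, stated in `training_config()`. The learning-rate
default is 10⁻² after a pilot sweep on the synthetic benchmark
(2,000 cycles, 50 epochs): at 10⁻³ the network is still far from converged
at that budget (reconstruction error ~3× higher, generated-cycle MMD ~5×
higher), 10⁻² converges several times faster with no instability, and
larger rates (1.5–3 × 10⁻²) are already worse. No data augmentation is
performed. Shuffling, the
validation split, weight initialization (via `model_config(seed = )`) and
the reparameterization draws all derive from explicit seeds; training is
bit-reproducible, and a non-finite loss aborts immediately naming the epoch
and batch.

Batch-normalization statistics deserve a note: training mode uses batch
moments and updates running statistics (momentum 0.9); generation, feature
extraction and evaluation always run in inference mode with the running
statistics, so `vae_encode()`, `vae_decode()` and everything built on them
are deterministic functions. Max-pooling breaks ties toward the earlier
sample; convolution padding is "same" so pooling alone controls length.

## The synthetic benchmark

Every test runs against a built-in simulator rather than downloaded
recordings. A cycle is a sum of Gaussian bumps — P (0.15 mV, 160 ms, width
25 ms), Q (−0.10, 370, 8), R (1.00, 400, 10), S (−0.15, 430, 8), T (0.30,
600, 40) — plus optional i.i.d. Gaussian sample noise; these morphology
values are fixture conventions in the style of textbook lead II, not
measurements. Beat-to-beat variability multiplies each wave parameter
(amplitude, center, width) by an independent `1 + N(0, jitter)` factor.
Because the center is an offset from the window start, a 5% jitter moves
the R peak by ±20 ms (sd) — the dominant source of variance, which makes
the benchmark a genuine test of whether the model learns *timing*, not just
amplitude. A consequence worth knowing: under timing jitter the pointwise
mean of many cycles is a smoothed template, so the simulator tests compare
Monte-Carlo means against a quadrature expectation over the jitter
distributions, not against the jitter-free template.

The study conditions used throughout the desk-scale suite are 2,000
training cycles at jitter 0.05 and noise 0.02 mV, with held-out references
from the same specification. Records for preprocessing tests concatenate
jittered cycles at a constant RR interval (RR variability is deliberately
not modelled — the method targets single cycles) and store the true R-peak
indices as annotations.

What the simulator does *not* emulate: real QRS sharpness (Gaussian R waves
are smoother), pathological morphologies, baseline wander, powerline
artifacts, inter-lead correlation, or RR-dependent shape changes. Passing
tests therefore demonstrate that the implementation is correct and that the
architecture can learn a controlled distribution — not that it reproduces
clinical ECG statistics. Headline numbers on real recordings additionally
depend on dataset, training length and kernel choices that the published
account leaves open.

## Evaluation

Generation quality is the squared maximum mean discrepancy between a
generated and a reference set under a Gaussian kernel,

> MMD²(X, Y) = E k(x, x′) + E k(y, y′) − 2 E k(x, y),
> k(x, y) = exp(−‖x − y‖² / 2σ²).

The kernel, bandwidth and estimator variant behind the published figure are
not stated, so the package defaults are declared instead and recorded in
every result: Gaussian kernel, biased (V-statistic) estimator — nonnegative,
exactly zero for identical sets — and the median heuristic σ = median
pairwise distance over the pooled sample (computed on an evenly spaced
subsample of at most 1,000 rows to bound memory; a degenerate all-equal
pool falls back to σ = 1). The unbiased estimator is available; it may be
slightly negative under the null, which the test suite exploits to check
its centering. `evaluate_model()` generates 3,000 cycles by default,
mirroring the published evaluation size.

## Latent traversal

`vae_traverse()` decodes a grid of latent vectors differing in exactly one
component (default grid: 7 points over [−3, 3], the prior's effective
support; the published grid is unstated). Which feature controls which wave
is a property of one trained model and is read off the plots by eye — the
package deliberately makes no automated claim, and the tests only assert
structural properties (non-constancy for a trained model, fidelity to the
base vector). For feature-activity judgments the package follows the
common variance convention: a latent dimension is "active" when the
variance of its encoder mean across inputs exceeds 0.01.

## Numerical and engineering choices

* The network is implemented in the package itself (R with small C++
  kernels for the convolution, pooling and batch-norm inner loops; each
  kernel tap is a BLAS `dgemm` on a pointer-offset submatrix, exploiting
  the batch-fastest array layout). The analytic backpropagation is verified
  against central finite differences to ~10⁻⁸ relative error in the test
  suite, and the compiled layers against direct R loop oracles.
* Weight initialization is He-normal, seeded; batch-norm ε = 10⁻⁵.
* Checkpoints serialize the architecture config, weights and running
  statistics under a versioned schema; loading reproduces encoder and
  decoder outputs bit-exactly, and any schema or shape mismatch is an
  explicit error.
* Inference on large batches is chunked (512 rows) to bound memory; results
  are identical to unchunked evaluation because every layer is
  row-independent in inference mode.
* The waveform-database reader/writer covers the subset needed here:
  format-16 signals, gain/baseline scaling, and beat annotations (any beat
  subtype is treated as an R peak); amplitudes quantize at 1/gain mV.
  Readers never resample — a non-500 Hz record is flagged in metadata and
  passed through.
* Problem sizes in the test suite were chosen to exercise the full method
  at desk scale: 2,000 training cycles × 50 epochs for the efficacy checks,
  3,000 generated cycles for the headline-style MMD, 500 + 500 rows × 20
  seeds for the MMD null calibration.

## Known limitations

Single-lead, single-cycle modelling only (per-lead models are obtained by
training one model per lead); no RR/rhythm modelling; no automated
wave-to-feature assignment; the built-in R-peak detector is a convenience,
not a validated clinical segmenter; and the published headline MMD is not
exactly reproducible from first principles because the original kernel
settings and data split are unspecified.
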