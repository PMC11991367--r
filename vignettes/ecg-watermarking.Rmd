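---
title: "Methods: VAE-based watermarking of synthetic ECG signals"
author: "ecgwatermark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VAE-based watermarking of synthetic ECG signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Problem and model

`ecgwatermark` studies how binary watermarks can be hidden in single-beat
electrocardiogram (ECG) signals with a small generative model, and how well
those watermarks survive measurement noise and an analog-style
signal-conditioning chain. Everything runs on synthetic data the package
generates itself, so every experiment is reproducible from a seed.

The generative core is a fully-connected variational autoencoder (VAE). The
encoder maps a signal $x \in \mathbb{R}^{90}$ through hidden layers of 128
and 64 rectified-linear units to the parameters of a Gaussian posterior
$q(z \mid x) = \mathcal{N}(\mu(x), \operatorname{diag}(\sigma^2(x)))$, with
$\log \sigma^2$ produced directly so that positivity is automatic. A latent
draw uses the reparameterization $z = \mu + \epsilon \odot \sigma$,
$\epsilon \sim \mathcal{N}(0, I)$, and the decoder mirrors the encoder
(64, 128 hidden units, linear output). Training minimizes

$$\mathcal{L} = \underbrace{\tfrac{1}{Bd}\sum (x - \hat x)^2}_{\text{reconstruction}}
 \;+\; \beta \cdot \underbrace{\tfrac{1}{B}\sum_b
 \left(-\tfrac12 \textstyle\sum_j (1 + \log\sigma_j^2 - \mu_j^2 - \sigma_j^2)\right)}_{\text{KL to } \mathcal{N}(0, I)}$$

The KL term is summed over latent dimensions and averaged over the batch;
the reconstruction term is averaged over both. This convention keeps
$\beta = 1$ meaningful at latent dimension 20: neither term is scaled by an
arbitrary factor of the input width. Gradients are derived by hand (the
network is six dense layers) and optimized with Adam at learning rate 0.001;
generic stochastic gradient descent is available behind
`vae_config(optimizer = "sgd")`, but Adam is the de-facto default for VAEs
and converges comfortably within the epoch budget.

## Synthetic beats

`synthesize_beat()` models one cardiac cycle as six Gaussian bumps
$a\,e^{-(t-c)^2/2w^2}$ on a flat isoelectric baseline — the standard
surrogate for simulated ECG morphology. The default template places
P (0.10 mV), Q (−0.12), R (1.00), S (−0.20), T (0.25) and U (0.04 mV) at
increasing beat fractions, keeps the R wave dominant, and keeps the U wave
below the 0.05 mV ceiling expected of normal beats. Bumps are wrapped at the
beat boundary so the beat is exactly one period of a periodic signal; an
optional `fourier_terms = K` path reconstructs the beat from its first $K$
harmonics, which makes the "sum of bumps" and "truncated Fourier series"
views interchangeable (they agree to machine precision once every harmonic
up to Nyquist is kept).

`generate_dataset()` normalizes the clean beat to $[-1, 1]$ first and then
adds i.i.d. zero-mean Gaussian noise with standard deviation equal to the
*noise factor*, i.e. noise acts in normalized amplitude units. The order
matters and is a deliberate choice: it makes noise factors comparable across
templates of different absolute amplitude. Per-signal seeds are derived from
the master seed with a counter scheme, so a dataset is reproducible and
independent of generation order. Splits default to 80/10/10
(validation/test sizes rounded to nearest, training takes the remainder).

What the generator does *not* emulate: heart-rate variability, beat-to-beat
morphology changes, baseline wander, powerline interference, electrode
artifacts, or pathological morphologies. Passing tests on this data shows
the pipeline's algebra and robustness margins are right; it does not certify
performance on clinical recordings.

## Watermarking strategies

All three schemes are **non-blind**: the embed record stores the reference
values needed for extraction.

* **Latent mean (μ):** shift $\mu' = \mu + \alpha w$ on the carrier
  coordinates (first $L$ coordinates by default; configurable), then decode.
  Extraction inverts $(\mu' - \mu)/\alpha$ and thresholds at 0.5 — the
  midpoint rule for 0/1 payloads.
* **Latent variable (z):** identical algebra applied to a sampled
  $z = \mu + \epsilon\sigma$. At the $\epsilon = 0$ draw the two latent
  strategies coincide exactly; the package uses $\epsilon = 0$ as the
  deterministic default and lets callers sample (`epsilon = NULL, seed =`)
  when they want the stochastic behavior.
* **Frequency domain:** after reconstruction, the magnitude of selected DFT
  bins (default bins 3..12, skipping DC and the fundamental) is increased by
  $\alpha$ for a 1-bit and decreased by $\alpha$ for a 0-bit (floored at
  $10^{-9}$ so magnitudes stay positive), phase preserved. Extraction
  compares the suspect's magnitudes against the stored originals.

### The two spectral update modes

`embed_freq()` exposes `conjugate_update`:

* `"none"` (default) modifies only the selected positive-frequency bins and
  takes the real part of the inverse transform. The real projection halves
  the effective per-bin shift, giving a time-domain distortion of exactly
  $L\alpha^2 / (2n^2)$ for an all-ones payload (Parseval). At $n = 90$,
  $L = 10$ this is $6.2\times10^{-6}$ at $\alpha = 0.1$ and
  $5.0\times10^{-4}$ at $\alpha = 0.9$ — the sub-$10^{-3}$ spread across the
  usual $\alpha$ grid that makes the frequency strategy attractive.
* `"mirror"` updates the conjugate-symmetric bins consistently, so the
  inverse transform is real to machine precision (imaginary residue below
  $10^{-9}$) and the full $\alpha$ shift survives in the output; distortion
  is $2L\alpha^2/n^2$, four times larger.

Both modes extract exactly from the stored reference. One caveat of the
default mode: a 0-bit whose magnitude is below $\alpha/4$ can flip sign
under the halved shift and read back as a 1; the mirror mode's floor avoids
this, which is why the filter-chain survival analysis uses it.

## Why the mean strategy is imperceptible — and why re-encoding fails

On noiseless data every training signal is identical, so the optimal decoder
outputs the beat regardless of $z$: the KL term drives the posterior toward
the prior and the decoder learns to ignore the latent input. This is exactly
what the α-insensitivity of the μ-strategy measures — shifting $\mu$ barely
changes the output. The same mechanism has a hard consequence: re-encoding
the watermarked signal cannot recover the payload, because the signal
carries almost no trace of the shift. `extract_mu(..., mode = "reencode")`
exists and is reported in `run_ber_table()`, but only the stored-reference
mode is exact by construction; the package asserts nothing about re-encode
accuracy.

## Metrics

* `mse()` — mean squared difference.
* `dtw_distance()` — classic dynamic-programming DTW with absolute-difference
  local cost, no window (a Sakoe-Chiba band is available), endpoints
  anchored. DTW is symmetric here but not a metric: the triangle inequality
  can fail, so the experiment tables only ever assert nonnegativity and
  monotonicity of DTW values, never metric identities.
* `snr_db()` — $-10\log_{10}(\sum(\hat s - s)^2 / \sum s^2)$, $+\infty$ for
  identical inputs (clean-reconstruction case) rather than an error.
* `ber_percent()` — percentage of mismatched bits; continuous extractions
  are thresholded upstream at 0.5.

## Sensor filter chain

The conditioning chain is modeled as Butterworth stages — 1 Hz high-pass,
10 Hz low-pass, 5–20 Hz band-pass, order 2 per stage (per edge for the
band-pass) — designed by bilinear transform at the dataset sample rate
(250 Hz default, inside the 200–500 Hz range typical of ECG acquisition).
Butterworth is the standard maximally-flat choice for ECG front-ends and
matches the smooth magnitude behavior expected of such a chain. Filtering is
causal by default, as a physical sensor is; `zero_phase = TRUE` switches to
forward-backward filtering. `bode_response()` evaluates the product of stage
transfer functions on a 256-point log grid over 0.1–100 Hz and unwraps the
phase; the full chain sweeps several hundred degrees of phase across that
band. Only the shape of the response is modeled — absolute gain of a
hardware realization would include amplifier stages this package does not
parameterize.

## Experiment sweeps and problem sizes

The sweep runners reproduce the study grids: embedding strengths
$\{0.1, 0.5, 0.9\}$, latent dimensions $\{10, 20, 30\}$, noise factors
$\{0.1, 0.3, 0.5\}$, a ten-bit all-ones payload. Every sweep trains one VAE
per replicate seed, reports per-seed rows plus medians and inter-seed
ranges, and is bit-reproducible under its base seed. Fidelity is always
reported against two references — the training signal and the unwatermarked
reconstruction — because comparisons of either kind are informative and they
differ by the reconstruction error.

Desk-scale defaults are 200 signals and 200 training epochs, which this
implementation reaches in a few seconds per run while reproducing the
order of magnitude of the reference fidelity values; the latent-dimension
stability claim (mean-strategy MSE below $10^{-4}$) is checked at the full
400-epoch setting (`full = TRUE`), since at 200 epochs the residual
*reconstruction* error of some seeds sits near $10^{-4}$ and would be
misattributed to the watermark. The z-strategy's sensitivity to $\alpha$ is
reported but not asserted: its distortion is dominated by the
reparameterization draw and is only monotone in $\alpha$ in expectation,
which the test suite checks statistically (paired draws, 3-standard-error
bound).

`run_ber_table()` uses a small nonzero noise factor (0.01) by default so its
eight test signals are distinct realizations; its absolute SNR levels depend
on training stochasticity and are not comparable across implementations —
the reproducible content is the all-zero stored-reference BER column.

## Numerical choices and degenerate inputs

* Normalization round-trips are exact to $10^{-12}$; constant signals are
  guarded (scale recorded as 1) in both normalization modes.
* `add_noise` and all seeded helpers restore the caller's RNG state.
* Training aborts with a diagnostic on non-finite loss instead of silently
  producing NaN parameters; early stopping (patience 50 on validation loss)
  is available but off by default so the full epoch budget is reproduced.
* Weight initialization is the uniform fan-in scheme under the config seed;
  two runs with equal seeds produce bit-identical parameters and loss
  curves on the same platform.
* The DC bin and Nyquist bin are rejected as payload carriers; payload bins
  must lie in the first half of the spectrum.

## Limitations

Synthetic single-beat data only; non-blind extraction only (references must
be stored); no encryption or key management of the payload; no wavelet-domain
embedding; filter modeling stops at transfer-function shape. Conclusions
about robustness transfer to real ECG only to the extent that the additive
Gaussian noise and linear filtering used here dominate real acquisition
artifacts.
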