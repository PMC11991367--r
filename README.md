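# ecgwatermark

Digital watermarking of synthetic ECG signals with a variational
autoencoder, in R.

Protecting the integrity and provenance of physiological recordings is a
practical concern wherever ECG data moves between devices, records systems
and research pipelines. This package implements and evaluates a
watermarking framework for single-beat ECG signals: a small fully-connected
VAE learns the beat, and a binary payload is hidden in one of three ways —

* **latent mean (μ):** shift the encoder's posterior mean,
  `μ' = μ + α·w`, and decode;
* **latent variable (z):** shift a sampled latent point,
  `z' = z + α·w`, and decode;
* **frequency domain:** after reconstruction, raise (bit 1) or lower
  (bit 0) the magnitude of selected DFT bins by `α`, phase preserved.

All schemes are non-blind: an embed record stores the reference values, and
stored-reference extraction inverts the embedding exactly (bit-error rate
0 for any payload and any `α > 0`). Evaluation covers mean squared error,
dynamic time warping distance, signal-to-noise ratio (dB) and bit-error
rate (%), plus a Butterworth model of an ECG sensor conditioning chain
(1 Hz high-pass, 10 Hz low-pass, 5–20 Hz band-pass) with Bode analysis for
watermark-survival studies.

Everything runs on Fourier-simulated beats the package generates itself
(P/Q/R/S/T/U Gaussian-bump morphology, additive Gaussian noise under a
"noise factor", 80/10/10 splits), so every number below reproduces from a
seed. The VAE — including backpropagation and Adam — is implemented in
plain R matrix algebra; a 200-epoch training run takes a few seconds.

## Worked example

```r
library(ecgwatermark)

ds    <- generate_dataset(n_signals = 200, noise_factor = 0, seed = 7)
model <- vae_train(vae(vae_config(seed = 7, epochs = 200)), ds$train)

x     <- ds$train[1, ]
recon <- vae_reconstruct(model, x)
mse(x, recon)
#> [1] 2.49459e-05

rec <- embed_mu(model, x, watermark_bits(), alpha = 0.1)  # ten 1-bits
mse(x, rec$watermarked)
#> [1] 2.651631e-05
ber_percent(watermark_bits(), extract_mu(rec, mode = "stored"))
#> [1] 0

rec_f <- embed_freq(recon, watermark_bits(), alpha = 0.5)
mse(recon, rec_f$watermarked)          # exactly L*alpha^2 / (2*n^2)
#> [1] 0.000154321
ber_percent(watermark_bits(), extract_freq(rec_f))
#> [1] 0
```

The reconstruction error (~2.5e-5) barely moves when the μ-watermark is
added — the trained decoder is nearly insensitive to latent shifts, which
is what makes this strategy imperceptible — and the frequency-domain
distortion follows a closed form in `α`. Extraction recovers the payload
exactly in both cases.

Sweeps over strength, latent dimension and noise:

```r
cfg <- sweep_config(n_seeds = 3)
run_alpha_sweep(cfg)$alpha_spread    # MSE spread across alpha per strategy
run_latent_dim_sweep(cfg)$summary
run_noise_sweep(cfg)$summary
run_ber_table(cfg)                   # per-signal SNR + BER, both extraction modes
```

A thin command-line front end lives at `inst/cli/ecgwm.R`
(`simulate`, `train`, `embed`, `extract`, `evaluate`, `bode`, `condition`,
`reproduce`).

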