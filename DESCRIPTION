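Package: ecgwatermark
Title: Digital Watermarking of Synthetic ECG Signals with a Variational
    Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates Fourier-simulated single-beat electrocardiogram (ECG)
    signals, trains a small fully-connected variational autoencoder (VAE) on
    them, and embeds binary watermarks into the signals by three strategies:
    shifting the latent posterior mean, shifting the sampled latent variable,
    and modifying selected discrete Fourier magnitudes of the reconstruction.
    Includes fidelity and detection metrics (mean squared error, dynamic time
    warping distance, signal-to-noise ratio, bit-error rate), a Butterworth
    model of an ECG sensor signal-conditioning chain with Bode analysis, and
    reproducible experiment sweeps over embedding strength, latent dimension
    and noise level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
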