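#' Configuration for the experiment sweeps
#'
#' Collects the grids and base parameters shared by the sweep runners. The
#' defaults follow the study conditions: embedding strengths
#' \{0.1, 0.5, 0.9\}, latent dimensions \{10, 20, 30\}, noise factors
#' \{0.1, 0.3, 0.5\}, a ten-bit all-ones payload, 90-sample signals, latent
#' dimension 20, learning rate 0.001 and batch size 32. `n_signals` and
#' `epochs` set the desk-scale problem size used by the runners; pass
#' `full = TRUE` to a runner for the full 400-epoch setting.
#'
#' @param alphas embedding strengths to sweep.
#' @param latent_dims latent dimensions to sweep.
#' @param noise_factors noise factors to sweep.
#' @param n_seeds replicate seeds per grid point.
#' @param base_seed master seed the replicate seeds are derived from.
#' @param n_signals dataset size per training run.
#' @param epochs desk-scale training epochs.
#' @param latent_dim base latent dimension (used where not swept).
#' @param n_samples signal length.
#' @param sampling_rate sampling rate in Hz.
#' @param bits watermark payload.
#' @param template beat morphology template.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(alphas = c(0.1, 0.5, 0.9),
                         latent_dims = c(10L, 20L, 30L),
                         noise_factors = c(0.1, 0.3, 0.5),
                         n_seeds = 5L, base_seed = 1L,
                         n_signals = 200L, epochs = 200L,
                         latent_dim = 20L, n_samples = 90L,
                         sampling_rate = 250,
                         bits = watermark_bits(),
                         template = beat_template()) {
  if (length(alphas) == 0L || length(latent_dims) == 0L ||
      length(noise_factors) == 0L)
    stop("sweep grids must be nonempty", call. = FALSE)
  for (a in alphas) .check_number(a, "alphas", lower = 1e-12)
  latent_dims <- vapply(latent_dims, .check_count, integer(1), name = "latent_dims")
  for (nf in noise_factors) .check_number(nf, "noise_factors", lower = 0)
  n_seeds <- .check_count(n_seeds, "n_seeds", lower = 1L)
  structure(list(alphas = as.numeric(alphas), latent_dims = latent_dims,
                 noise_factors = as.numeric(noise_factors),
                 n_seeds = n_seeds,
                 base_seed = .check_count(base_seed, "base_seed", lower = 0L),
                 n_signals = .check_count(n_signals, "n_signals", lower = 10L),
                 epochs = .check_count(epochs, "epochs", lower = 1L),
                 latent_dim = .check_count(latent_dim, "latent_dim", lower = 1L),
                 n_samples = .check_count(n_samples, "n_samples", lower = 16L),
                 sampling_rate = sampling_rate,
                 bits = .check_bits(bits), template = template),
            class = "sweep_config")
}

# seeds for the replicate runs of one sweep
.sweep_seeds <- function(cfg) {
  vapply(seq_len(cfg$n_seeds),
         function(k) as.integer(.child_seed(cfg$base_seed, k) %% 1e6 + 1),
         integer(1))
}

# one dataset + trained model for given conditions
.train_run <- function(cfg, seed, latent_dim = cfg$latent_dim,
                       noise_factor = 0, epochs = cfg$epochs) {
  ds <- generate_dataset(template = cfg$template, n_signals = cfg$n_signals,
                         noise_factor = noise_factor, seed = seed,
                         n_samples = cfg$n_samples,
                         sampling_rate = cfg$sampling_rate)
  vc <- vae_config(input_dim = cfg$n_samples, latent_dim = latent_dim,
                   epochs = epochs, seed = seed)
  model <- vae_train(vae(vc), ds$train)
  list(ds = ds, model = model)
}

# watermarked reconstruction of x under one strategy
.embed_by <- function(strategy, model, x, bits, alpha) {
  switch(strategy,
         mu = embed_mu(model, x, bits, alpha),
         z = embed_z(model, x, bits, alpha),
         freq = {
           recon <- vae_reconstruct(model, x)
           embed_freq(recon, bits, alpha)
         },
         stop("unknown strategy: ", strategy, call. = FALSE))
}

.summarize <- function(df, by, value_cols) {
  agg <- stats::aggregate(df[value_cols], df[by], function(v)
    c(median = stats::median(v), min = min(v), max = max(v)))
  # flatten the matrix columns aggregate() produces
  out <- agg[by]
  for (vc in value_cols) {
    m <- agg[[vc]]
    out[[paste0(vc, "_median")]] <- m[, "median"]
    out[[paste0(vc, "_range")]] <- m[, "max"] - m[, "min"]
  }
  out
}

#' Sweep embedding strength against fidelity
#'
#' For each replicate seed a VAE is trained on a noiseless dataset; the
#' ten-bit payload is then embedded at every strength in `cfg$alphas` with
#' each of the three strategies. Two fidelity columns are reported for every
#' run: `mse_train` compares the watermarked output with the training
#' signal, `mse_recon` with the unwatermarked reconstruction; `dtw_train` is
#' the warping distance to the training signal.
#'
#' @param cfg a [sweep_config()].
#' @param strategies subset of `c("mu", "z", "freq")`.
#' @param full use the full 400-epoch setting instead of `cfg$epochs`.
#' @return list with `results` (one row per seed, strategy and alpha),
#'   `summary` (medians and inter-seed ranges) and `alpha_spread` (per
#'   strategy, the spread of the median MSE across the alpha grid).
#' @export
run_alpha_sweep <- function(cfg = sweep_config(),
                            strategies = c("mu", "z", "freq"),
                            full = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  strategies <- match.arg(strategies, several.ok = TRUE)
  epochs <- if (full) 400L else cfg$epochs
  seeds <- .sweep_seeds(cfg)
  rows <- list()
  for (seed in seeds) {
    run <- .train_run(cfg, seed, noise_factor = 0, epochs = epochs)
    x_ref <- run$ds$train[1, ]
    recon <- vae_reconstruct(run$model, x_ref)
    for (strategy in strategies) {
      for (alpha in cfg$alphas) {
        rec <- .embed_by(strategy, run$model, x_ref, cfg$bits, alpha)
        wm <- as.numeric(rec$watermarked)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategy, alpha = alpha, seed = seed,
          mse_train = mse(x_ref, wm), mse_recon = mse(recon, wm),
          dtw_train = dtw_distance(x_ref, wm))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- .summarize(results, c("strategy", "alpha"),
                        c("mse_train", "mse_recon", "dtw_train"))
  spread <- stats::aggregate(mse_train_median ~ strategy, summary,
                             function(v) max(v) - min(v))
  names(spread)[2] <- "mse_spread"
  list(results = results, summary = summary, alpha_spread = spread)
}

#' Sweep latent dimension against fidelity
#'
#' Trains one VAE per seed and latent dimension on noiseless data and embeds
#' the payload at the first strength of the alpha grid using the latent-mean
#' and latent-variable strategies.
#'
#' @inheritParams run_alpha_sweep
#' @return list with `results` and `summary` tables.
#' @export
run_latent_dim_sweep <- function(cfg = sweep_config(),
                                 strategies = c("mu", "z"),
                                 full = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  strategies <- match.arg(strategies, several.ok = TRUE)
  epochs <- if (full) 400L else cfg$epochs
  alpha <- cfg$alphas[1]
  seeds <- .sweep_seeds(cfg)
  rows <- list()
  for (seed in seeds) {
    for (ld in cfg$latent_dims) {
      run <- .train_run(cfg, seed, latent_dim = ld, noise_factor = 0,
                        epochs = epochs)
      x_ref <- run$ds$train[1, ]
      recon <- vae_reconstruct(run$model, x_ref)
      for (strategy in strategies) {
        rec <- .embed_by(strategy, run$model, x_ref, cfg$bits, alpha)
        wm <- as.numeric(rec$watermarked)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategy, latent_dim = ld, alpha = alpha, seed = seed,
          mse_train = mse(x_ref, wm), mse_recon = mse(recon, wm))
      }
    }
  }
  results <- do.call(rbind, rows)
  list(results = results,
       summary = .summarize(results, c("strategy", "latent_dim"),
                            c("mse_train", "mse_recon")))
}

#' Sweep noise factor against fidelity
#'
#' For each noise factor and seed a VAE is trained on the noisy dataset and
#' three signals are compared pairwise by MSE and DTW: (a) the first training
#' signal, (b) the mean of all training signals, and (c) the watermarked
#' reconstruction of the first training signal.
#'
#' @inheritParams run_alpha_sweep
#' @param alpha embedding strength used for the watermarked reconstruction.
#' @return list with `results` (columns `mse_ab`, `mse_ac`, `mse_bc`,
#'   `dtw_ab`, `dtw_ac`, `dtw_bc`) and `summary` (medians per strategy and
#'   noise factor).
#' @export
run_noise_sweep <- function(cfg = sweep_config(),
                            strategies = c("mu", "z", "freq"),
                            alpha = NULL, full = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  strategies <- match.arg(strategies, several.ok = TRUE)
  epochs <- if (full) 400L else cfg$epochs
  if (is.null(alpha)) alpha <- cfg$alphas[1]
  seeds <- .sweep_seeds(cfg)
  rows <- list()
  for (nf in cfg$noise_factors) {
    for (seed in seeds) {
      run <- .train_run(cfg, seed, noise_factor = nf, epochs = epochs)
      a_sig <- run$ds$train[1, ]
      b_sig <- colMeans(run$ds$train)
      for (strategy in strategies) {
        rec <- .embed_by(strategy, run$model, a_sig, cfg$bits, alpha)
        c_sig <- as.numeric(rec$watermarked)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategy, noise_factor = nf, seed = seed,
          mse_ab = mse(a_sig, b_sig), mse_ac = mse(a_sig, c_sig),
          mse_bc = mse(b_sig, c_sig),
          dtw_ab = dtw_distance(a_sig, b_sig),
          dtw_ac = dtw_distance(a_sig, c_sig),
          dtw_bc = dtw_distance(b_sig, c_sig))
      }
    }
  }
  results <- do.call(rbind, rows)
  list(results = results,
       summary = .summarize(results, c("strategy", "noise_factor"),
                            c("mse_ab", "mse_ac", "mse_bc",
                              "dtw_ab", "dtw_ac", "dtw_bc")))
}

#' Per-signal SNR and BER table for the latent-mean method
#'
#' Trains one VAE, embeds the payload into each of `n_rows` test signals
#' with the latent-mean strategy, and reports the transparency (SNR between
#' the unwatermarked reconstruction and the watermarked signal) together
#' with the bit-error rate of stored-reference extraction and, separately,
#' of re-encode extraction.
#'
#' @inheritParams run_alpha_sweep
#' @param n_rows number of test signals to report.
#' @param alpha embedding strength.
#' @param noise_factor dataset noise factor; a small nonzero default makes
#'   the test signals distinct realizations.
#' @return data frame with columns `signal_id`, `snr_db`, `ber_stored`,
#'   `ber_reencode`.
#' @export
run_ber_table <- function(cfg = sweep_config(), n_rows = 8L, alpha = NULL,
                          noise_factor = 0.01, full = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  n_rows <- .check_count(n_rows, "n_rows", lower = 1L)
  if (is.null(alpha)) alpha <- cfg$alphas[1]
  epochs <- if (full) 400L else cfg$epochs
  run <- .train_run(cfg, .sweep_seeds(cfg)[1], noise_factor = noise_factor,
                    epochs = epochs)
  test <- run$ds$test
  if (nrow(test) < n_rows)
    stop(sprintf("dataset has only %d test signals (%d requested): increase n_signals",
                 nrow(test), n_rows), call. = FALSE)
  rows <- lapply(seq_len(n_rows), function(i) {
    x <- test[i, ]
    recon <- vae_reconstruct(run$model, x)
    rec <- embed_mu(run$model, x, cfg$bits, alpha)
    data.frame(
      signal_id = i,
      snr_db = snr_db(recon, as.numeric(rec$watermarked)),
      ber_stored = ber_percent(cfg$bits, extract_mu(rec, mode = "stored")),
      ber_reencode = ber_percent(cfg$bits,
                                 extract_mu(rec, model = run$model,
                                            mode = "reencode")))
  })
  do.call(rbind, rows)
}
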