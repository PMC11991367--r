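#' Single-beat ECG morphology template
#'
#' Describes one cardiac cycle as six localized waves (P, Q, R, S, T, U) on a
#' flat isoelectric baseline. Each wave is a Gaussian bump
#' `a * exp(-(t - c)^2 / (2 w^2))` where `t` is the position within the beat
#' expressed as a fraction in `[0, 1)`.
#'
#' The default parameters give a physiologically plausible normal beat: the R
#' wave is the dominant positive deflection, Q and S are the small negative
#' deflections flanking it, the T wave is a broad positive repolarization wave
#' and the U wave is wide and low with an amplitude below 0.05 mV.
#'
#' @param amplitudes named numeric vector of signed wave amplitudes in mV, in
#'   the order P, Q, R, S, T, U.
#' @param centers named numeric vector of wave centers as fractions of the
#'   beat in `[0, 1)`, strictly increasing P < Q < R < S < T < U.
#' @param widths named numeric vector of Gaussian widths (standard deviations)
#'   as fractions of the beat, all positive.
#' @param baseline_level isoelectric baseline level in mV.
#'
#' @return An object of class `beat_template`.
#' @examples
#' tpl <- beat_template()
#' beat <- synthesize_beat(tpl, n_samples = 90, sampling_rate = 250)
#' @export
beat_template <- function(amplitudes = c(P = 0.10, Q = -0.12, R = 1.00,
                                         S = -0.20, T = 0.25, U = 0.04),
                          centers = c(P = 0.20, Q = 0.36, R = 0.40,
                                      S = 0.44, T = 0.62, U = 0.78),
                          widths = c(P = 0.025, Q = 0.010, R = 0.012,
                                     S = 0.010, T = 0.040, U = 0.030),
                          baseline_level = 0) {
  waves <- c("P", "Q", "R", "S", "T", "U")
  for (v in list(amplitudes, centers, widths)) {
    if (!is.numeric(v) || length(v) != 6L || !all(is.finite(v)))
      stop("wave parameter vectors must be 6 finite numbers (P,Q,R,S,T,U)",
           call. = FALSE)
  }
  amplitudes <- stats::setNames(as.numeric(amplitudes), waves)
  centers <- stats::setNames(as.numeric(centers), waves)
  widths <- stats::setNames(as.numeric(widths), waves)
  if (any(widths <= 0))
    stop("all wave widths must be > 0", call. = FALSE)
  if (any(centers < 0) || any(centers >= 1))
    stop("wave centers must lie in [0, 1)", call. = FALSE)
  if (any(diff(centers) <= 0))
    stop("wave centers must strictly increase in the order P < Q < R < S < T < U",
         call. = FALSE)
  pos <- amplitudes[amplitudes > 0]
  if (length(pos) == 0L || names(which.max(amplitudes)) != "R")
    stop("the R wave must carry the largest positive amplitude", call. = FALSE)
  .check_number(baseline_level, "baseline_level")
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths,
                 baseline_level = baseline_level),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat("Single-beat ECG template (mV / beat fractions)\n")
  print(data.frame(wave = names(x$amplitudes), amplitude_mV = x$amplitudes,
                   center = x$centers, width = x$widths, row.names = NULL))
  cat("baseline:", x$baseline_level, "mV\n")
  invisible(x)
}

#' Synthesize a clean single-beat ECG signal
#'
#' Evaluates the template's six Gaussian wave components on a uniform sample
#' grid over one beat (or `n_beats` identical beats). Optionally the beat is
#' re-expressed through its truncated Fourier series: the periodic extension
#' of the beat is transformed, harmonics above `fourier_terms` are dropped,
#' and the signal is reconstructed from the remaining ones. With enough
#' harmonics the two views coincide; a small `fourier_terms` yields a
#' band-limited, smoothed beat.
#'
#' @param template a [beat_template()].
#' @param n_samples total number of samples (at least 16); must be divisible
#'   by `n_beats`.
#' @param sampling_rate sampling rate in Hz.
#' @param n_beats number of identical concatenated beats.
#' @param fourier_terms `NULL` for the direct Gaussian-bump evaluation, or the
#'   number of harmonics `K >= 1` retained in the truncated Fourier
#'   reconstruction of the periodic beat.
#'
#' @return An `ecg_signal`: a numeric vector of samples (mV) with attribute
#'   `sampling_rate`.
#' @examples
#' x <- synthesize_beat(beat_template(), n_samples = 90, sampling_rate = 250)
#' which.max(x)  # R-wave sample
#' @export
synthesize_beat <- function(template, n_samples = 90L, sampling_rate = 250,
                            n_beats = 1L, fourier_terms = NULL) {
  if (!inherits(template, "beat_template"))
    stop("`template` must be a beat_template", call. = FALSE)
  n_samples <- .check_count(n_samples, "n_samples", lower = 16L)
  n_beats <- .check_count(n_beats, "n_beats", lower = 1L)
  .check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  if (n_samples %% n_beats != 0L)
    stop("`n_samples` must be divisible by `n_beats`", call. = FALSE)
  n <- n_samples %/% n_beats
  tt <- (seq_len(n) - 1) / n  # beat fraction in [0, 1)
  beat <- rep(template$baseline_level, n)
  for (wv in names(template$amplitudes)) {
    a <- template$amplitudes[[wv]]
    c0 <- template$centers[[wv]]
    w <- template$widths[[wv]]
    # wrap the bump around the beat boundary so the periodic extension is smooth
    d <- tt - c0
    d <- d - round(d)
    beat <- beat + a * exp(-d^2 / (2 * w^2))
  }
  if (!is.null(fourier_terms)) {
    k <- .check_count(fourier_terms, "fourier_terms", lower = 1L)
    X <- stats::fft(beat)
    keep <- rep(FALSE, n)
    keep[1] <- TRUE                       # DC
    idx <- seq_len(min(k, floor(n / 2)))  # harmonics 1..K and conjugates
    keep[1 + idx] <- TRUE
    keep[n + 1 - idx] <- TRUE
    X[!keep] <- 0 + 0i
    beat <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  ecg_signal(rep(beat, n_beats), sampling_rate)
}

#' Construct an ECG signal object
#'
#' @param samples numeric vector of finite samples (mV).
#' @param sampling_rate sampling rate in Hz.
#' @return numeric vector of class `ecg_signal` with a `sampling_rate`
#'   attribute.
#' @export
ecg_signal <- function(samples, sampling_rate = 250) {
  samples <- .check_signal(samples, "samples")
  .check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  structure(samples, sampling_rate = sampling_rate, class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("ECG signal: %d samples at %g Hz (%.3f s), range [%.4g, %.4g] mV\n",
              length(x), attr(x, "sampling_rate"),
              length(x) / attr(x, "sampling_rate"), min(x), max(x)))
  invisible(x)
}

#' Add zero-mean Gaussian noise to a signal
#'
#' The noise factor is the standard deviation of i.i.d. Gaussian noise added
#' per sample, in the same (normalized) amplitude units as the signal.
#'
#' @param x numeric signal.
#' @param noise_factor noise standard deviation, `>= 0`.
#' @param seed optional integer seed; the call is reproducible given the seed
#'   and does not disturb the caller's RNG state.
#' @return the noisy signal, same length and attributes.
#' @export
add_noise <- function(x, noise_factor, seed = NULL) {
  xs <- .check_signal(x, "x")
  .check_number(noise_factor, "noise_factor", lower = 0)
  if (noise_factor == 0) return(x)
  eps <- if (is.null(seed)) {
    stats::rnorm(length(xs))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    stats::rnorm(length(xs))
  }
  out <- xs + noise_factor * eps
  attributes(out) <- attributes(x)
  out
}

#' Normalize signals with an invertible record
#'
#' Computes one global affine map over all supplied values and applies it to
#' every sample, returning the transformed signals together with the record
#' needed to invert the map exactly.
#'
#' Modes: `"minus-one-to-one"` maps the observed range onto `[-1, 1]`;
#' `"zscore"` centers to mean 0, standard deviation 1; `"none"` is the
#' identity. Degenerate (constant) input is guarded: the scale is recorded as
#' 1 and only the offset is removed.
#'
#' @param x numeric vector or matrix (one signal per row).
#' @param mode normalization mode.
#' @return `list(signals, record)`; `record` is of class `norm_record`.
#' @seealso [denormalize_signals()]
#' @export
normalize_signals <- function(x, mode = c("minus-one-to-one", "zscore", "none")) {
  mode <- match.arg(mode)
  xm <- .as_signal_matrix(x)
  if (!all(is.finite(xm))) stop("signals contain non-finite samples", call. = FALSE)
  if (mode == "none") {
    record <- structure(list(mode = mode, center = 0, scale = 1), class = "norm_record")
    return(list(signals = x, record = record))
  }
  if (mode == "minus-one-to-one") {
    lo <- min(xm); hi <- max(xm)
    if (hi > lo) {
      center <- (hi + lo) / 2
      scale <- (hi - lo) / 2
    } else {
      center <- lo; scale <- 1
    }
  } else {
    center <- mean(xm)
    s <- stats::sd(as.vector(xm))
    scale <- if (is.finite(s) && s > 0) s else 1
  }
  out <- (x - center) / scale
  attributes(out) <- attributes(x)
  record <- structure(list(mode = mode, center = center, scale = scale),
                      class = "norm_record")
  list(signals = out, record = record)
}

#' Invert a normalization
#'
#' @param x normalized signals (vector or matrix).
#' @param record the `norm_record` returned by [normalize_signals()].
#' @return signals on the original scale.
#' @export
denormalize_signals <- function(x, record) {
  if (!inherits(record, "norm_record"))
    stop("`record` must be a norm_record", call. = FALSE)
  out <- x * record$scale + record$center
  attributes(out) <- attributes(x)
  out
}

#' Generate a reproducible synthetic ECG dataset
#'
#' Builds `n_signals` independent noisy realizations of the same clean beat
#' and partitions them into training, validation and test sets. The clean
#' beat is normalized first (so the noise factor acts in normalized amplitude
#' units), then per-signal Gaussian noise is added using per-signal seeds
#' derived from the master seed by a counter scheme, making the dataset
#' reproducible and independent of generation order.
#'
#' Partition sizes: validation and test sizes are the split fractions rounded
#' to the nearest integer; training receives the remainder.
#'
#' @param template a [beat_template()].
#' @param n_signals number of signals (at least 10).
#' @param noise_factor Gaussian noise standard deviation in normalized units.
#' @param seed master integer seed.
#' @param normalization_mode passed to [normalize_signals()].
#' @param split_fractions train/validation/test fractions summing to 1.
#' @param n_samples samples per signal.
#' @param sampling_rate sampling rate in Hz.
#'
#' @return An object of class `ecg_dataset`: list with matrices `train`,
#'   `val`, `test` (one signal per row), the normalized clean beat `clean`,
#'   the normalization `record`, and the generation parameters.
#' @examples
#' ds <- generate_dataset(n_signals = 100, noise_factor = 0.05, seed = 1)
#' nrow(ds$train)  # 80
#' @export
generate_dataset <- function(template = beat_template(), n_signals = 200L,
                             noise_factor = 0, seed = 1L,
                             normalization_mode = "minus-one-to-one",
                             split_fractions = c(0.8, 0.1, 0.1),
                             n_samples = 90L, sampling_rate = 250) {
  n_signals <- .check_count(n_signals, "n_signals", lower = 10L)
  .check_number(noise_factor, "noise_factor", lower = 0)
  seed <- .check_count(seed, "seed", lower = 0L)
  if (!is.numeric(split_fractions) || length(split_fractions) != 3L ||
      any(split_fractions < 0))
    stop("`split_fractions` must be 3 nonnegative numbers", call. = FALSE)
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop("`split_fractions` must sum to 1 (tolerance 1e-9)", call. = FALSE)

  clean_raw <- synthesize_beat(template, n_samples = n_samples,
                               sampling_rate = sampling_rate)
  nrm <- normalize_signals(as.numeric(clean_raw), mode = normalization_mode)
  clean <- nrm$signals

  sig <- matrix(0, nrow = n_signals, ncol = n_samples)
  for (i in seq_len(n_signals)) {
    sig[i, ] <- add_noise(clean, noise_factor,
                          seed = .child_seed(seed, i))
  }

  n_val <- round(split_fractions[2] * n_signals)
  n_test <- round(split_fractions[3] * n_signals)
  n_train <- n_signals - n_val - n_test
  if (n_train < 1L)
    stop("split leaves no training signals", call. = FALSE)
  idx_train <- seq_len(n_train)
  idx_val <- seq_len(n_val) + n_train
  idx_test <- seq_len(n_test) + n_train + n_val

  structure(list(
    train = sig[idx_train, , drop = FALSE],
    val = sig[idx_val, , drop = FALSE],
    test = sig[idx_test, , drop = FALSE],
    clean = clean,
    record = nrm$record,
    template = template,
    noise_factor = noise_factor,
    seed = seed,
    normalization_mode = normalization_mode,
    split_fractions = split_fractions,
    sampling_rate = sampling_rate
  ), class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic ECG dataset: %d/%d/%d train/val/test, %d samples @ %g Hz, noise factor %g, seed %d\n",
    nrow(x$train), nrow(x$val), nrow(x$test), ncol(x$train),
    x$sampling_rate, x$noise_factor, x$seed))
  invisible(x)
}

#' Read and write signals as delimited text
#'
#' Signals are stored one per row as comma-separated values without a header.
#'
#' @param x numeric vector or matrix of signals (one per row).
#' @param path file path.
#' @return `write_signals` returns `path` invisibly; `read_signals` returns a
#'   numeric matrix (one signal per row).
#' @export
write_signals <- function(x, path) {
  xm <- .as_signal_matrix(x)
  utils::write.table(xm, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @param header logical: does the file carry a header row to skip?
#' @export
read_signals <- function(path, header = FALSE) {
  m <- as.matrix(utils::read.csv(path, header = header))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
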