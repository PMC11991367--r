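#' Binary watermark payload
#'
#' @param bits vector of 0/1 values (logical or numeric). The default is the
#'   ten-bit all-ones payload.
#' @param length_out when `bits` is omitted, the length of the all-ones
#'   payload.
#' @return integer vector of class `watermark_bits`.
#' @export
watermark_bits <- function(bits = NULL, length_out = 10L) {
  if (is.null(bits)) {
    length_out <- .check_count(length_out, "length_out", lower = 1L)
    bits <- rep(1L, length_out)
  }
  if (is.logical(bits)) bits <- as.integer(bits)
  if (!is.numeric(bits) || length(bits) < 1L || !all(bits %in% c(0, 1)))
    stop("`bits` must be a non-empty vector over {0, 1}", call. = FALSE)
  structure(as.integer(bits), class = "watermark_bits")
}

.check_bits <- function(bits) {
  if (!inherits(bits, "watermark_bits")) bits <- watermark_bits(bits)
  bits
}

.new_record <- function(strategy, alpha, bits, indices, reference,
                        watermarked, extra = list()) {
  structure(c(list(strategy = strategy, alpha = alpha,
                   bits = as.integer(bits), indices = as.integer(indices),
                   reference = as.numeric(reference),
                   watermarked = watermarked), extra),
            class = "wm_record")
}

#' @export
print.wm_record <- function(x, ...) {
  cat(sprintf("Watermark record: strategy %s, alpha %g, %d bits at indices %s\n",
              x$strategy, x$alpha, length(x$bits),
              paste(x$indices, collapse = ",")))
  invisible(x)
}

#' Embed a watermark into the latent posterior mean
#'
#' Encodes the signal, shifts the posterior mean by `alpha` at the carrier
#' coordinates holding 1-bits (`mu_w = mu + alpha * w`), draws the latent
#' variable `z = mu_w + epsilon * sigma` and decodes it. The scheme is
#' non-blind: the record stores the original mean needed for extraction.
#'
#' @param model a trained `ecg_vae`.
#' @param x one signal (numeric vector of length `input_dim`).
#' @param bits watermark payload, length at most `latent_dim`.
#' @param alpha embedding strength (> 0).
#' @param coords latent coordinates carrying the bits; default the first
#'   `length(bits)` coordinates.
#' @param epsilon reparameterization draw used when decoding; default 0
#'   (deterministic decode at the shifted mean). Pass `NULL` to sample.
#' @param seed seed for a sampled `epsilon`.
#' @return a `wm_record` with the watermarked signal, the stored reference
#'   mean and the shifted mean.
#' @export
embed_mu <- function(model, x, bits = watermark_bits(), alpha = 0.1,
                     coords = NULL, epsilon = 0, seed = NULL) {
  stopifnot(inherits(model, "ecg_vae"))
  bits <- .check_bits(bits)
  .check_number(alpha, "alpha", lower = 1e-300)
  L <- model$config$latent_dim
  if (length(bits) > L)
    stop(sprintf("watermark length %d exceeds latent capacity %d",
                 length(bits), L), call. = FALSE)
  if (is.null(coords)) coords <- seq_along(bits)
  coords <- vapply(coords, .check_count, integer(1), name = "coords")
  if (anyDuplicated(coords) || any(coords > L))
    stop("`coords` must be distinct latent coordinates within latent_dim",
         call. = FALSE)
  st <- vae_encode(model, x)
  mu <- drop(st$mu)
  mu_w <- mu
  mu_w[coords] <- mu_w[coords] + alpha * bits
  st_w <- structure(list(mu = matrix(mu_w, 1L), log_var = st$log_var),
                    class = "latent_stats")
  z <- vae_reparameterize(st_w, epsilon = epsilon, seed = seed)
  wm <- drop(vae_decode(model, z))
  .new_record("mu", alpha, bits, coords, reference = mu[coords],
              watermarked = wm, extra = list(mu_w = mu_w[coords]))
}

#' Extract a watermark embedded in the latent mean
#'
#' Recovers the continuous watermark `(mu_w - mu) / alpha` at the carrier
#' coordinates and thresholds at 0.5. In `"stored"` mode the shifted mean
#' saved at embedding time is used and recovery is exact; in `"reencode"`
#' mode the watermarked signal is passed through the encoder again, so
#' accuracy depends on how closely encode(decode(.)) is idempotent.
#'
#' @param record a `wm_record` with strategy `"mu"`.
#' @param model the VAE (required for `mode = "reencode"`).
#' @param mode `"stored"` or `"reencode"`.
#' @return recovered `watermark_bits`, with the continuous estimate attached
#'   as attribute `continuous`.
#' @export
extract_mu <- function(record, model = NULL, mode = c("stored", "reencode")) {
  mode <- match.arg(mode)
  if (!inherits(record, "wm_record") || record$strategy != "mu")
    stop("`record` must be a wm_record with strategy \"mu\"", call. = FALSE)
  if (record$alpha == 0) stop("alpha is zero: cannot invert the embedding",
                              call. = FALSE)
  mu_w <- if (mode == "stored") {
    record$mu_w
  } else {
    if (is.null(model)) stop("`model` is required for reencode mode", call. = FALSE)
    drop(vae_encode(model, record$watermarked)$mu)[record$indices]
  }
  w_cont <- (mu_w - record$reference) / record$alpha
  out <- watermark_bits(as.integer(w_cont >= 0.5))
  attr(out, "continuous") <- w_cont
  out
}

#' Embed a watermark into the sampled latent variable
#'
#' Draws `z_original = mu + epsilon * sigma`, shifts it by `alpha` at the
#' carrier coordinates (`z_w = z_original + alpha * w`) and decodes. With the
#' default `epsilon = 0` draw, `z_original = mu` and the result coincides
#' with [embed_mu()].
#'
#' @inheritParams embed_mu
#' @return a `wm_record` storing the original and shifted latent vectors.
#' @export
embed_z <- function(model, x, bits = watermark_bits(), alpha = 0.1,
                    coords = NULL, epsilon = 0, seed = NULL) {
  stopifnot(inherits(model, "ecg_vae"))
  bits <- .check_bits(bits)
  .check_number(alpha, "alpha", lower = 1e-300)
  L <- model$config$latent_dim
  if (length(bits) > L)
    stop(sprintf("watermark length %d exceeds latent capacity %d",
                 length(bits), L), call. = FALSE)
  if (is.null(coords)) coords <- seq_along(bits)
  coords <- vapply(coords, .check_count, integer(1), name = "coords")
  if (anyDuplicated(coords) || any(coords > L))
    stop("`coords` must be distinct latent coordinates within latent_dim",
         call. = FALSE)
  st <- vae_encode(model, x)
  z0 <- drop(vae_reparameterize(st, epsilon = epsilon, seed = seed))
  z_w <- z0
  z_w[coords] <- z_w[coords] + alpha * bits
  wm <- drop(vae_decode(model, matrix(z_w, 1L)))
  .new_record("z", alpha, bits, coords, reference = z0[coords],
              watermarked = wm, extra = list(z_w = z_w[coords]))
}

#' Extract a watermark embedded in the latent variable
#'
#' `(z_w - z_original) / alpha` at the carrier coordinates, thresholded at
#' 0.5. Modes as in [extract_mu()]; in `"reencode"` mode the watermarked
#' signal is re-encoded and its posterior mean stands in for `z_w`.
#'
#' @param record a `wm_record` with strategy `"z"`.
#' @inheritParams extract_mu
#' @return recovered `watermark_bits` with attribute `continuous`.
#' @export
extract_z <- function(record, model = NULL, mode = c("stored", "reencode")) {
  mode <- match.arg(mode)
  if (!inherits(record, "wm_record") || record$strategy != "z")
    stop("`record` must be a wm_record with strategy \"z\"", call. = FALSE)
  if (record$alpha == 0) stop("alpha is zero: cannot invert the embedding",
                              call. = FALSE)
  z_w <- if (mode == "stored") {
    record$z_w
  } else {
    if (is.null(model)) stop("`model` is required for reencode mode", call. = FALSE)
    drop(vae_encode(model, record$watermarked)$mu)[record$indices]
  }
  w_cont <- (z_w - record$reference) / record$alpha
  out <- watermark_bits(as.integer(w_cont >= 0.5))
  attr(out, "continuous") <- w_cont
  out
}

#' Embed a watermark in the frequency domain
#'
#' Takes the discrete Fourier transform of the (reconstructed) signal and
#' changes the magnitude of the selected coefficients: a 1-bit increases the
#' magnitude by `alpha`, a 0-bit decreases it by `alpha` (floored at
#' `magnitude_floor`), with the phase preserved. The watermarked signal is
#' the real part of the inverse transform.
#'
#' `conjugate_update` selects how the negative-frequency half of the spectrum
#' is treated. `"none"` (default) modifies only the selected
#' positive-frequency bins and takes the real part, so each bin's effective
#' magnitude shift in the real output is `alpha / 2`; the time-domain
#' distortion for payload bins is `MSE = L * alpha^2 / (2 * n^2)`. `"mirror"`
#' updates the conjugate-symmetric bins consistently, which keeps the inverse
#' transform real to machine precision (imaginary residue below 1e-9) and
#' doubles the per-bin shift; the distortion is `2 * L * alpha^2 / n^2`.
#'
#' @param x the signal to watermark (typically a VAE reconstruction).
#' @param bits watermark payload.
#' @param alpha additive magnitude change (> 0), in spectral magnitude units
#'   of the unnormalized DFT.
#' @param coeff_indices 1-based positions in the DFT vector; must exclude the
#'   DC bin (position 1) and the Nyquist bin and stay in the first half of
#'   the spectrum. Default: positions `3:(length(bits) + 2)`, skipping DC and
#'   the fundamental.
#' @param conjugate_update `"none"` or `"mirror"` (see Details).
#' @param magnitude_floor smallest magnitude a 0-bit may leave behind.
#' @return a `wm_record` storing the original magnitudes at the payload bins.
#' @export
embed_freq <- function(x, bits = watermark_bits(), alpha = 0.1,
                       coeff_indices = NULL,
                       conjugate_update = c("none", "mirror"),
                       magnitude_floor = 1e-9) {
  conjugate_update <- match.arg(conjugate_update)
  xs <- .check_signal(x, "x")
  bits <- .check_bits(bits)
  .check_number(alpha, "alpha", lower = 0)
  .check_number(magnitude_floor, "magnitude_floor", lower = 0)
  n <- length(xs)
  Lb <- length(bits)
  if (is.null(coeff_indices)) coeff_indices <- seq_len(Lb) + 2L
  coeff_indices <- as.integer(coeff_indices)
  if (length(coeff_indices) != Lb)
    stop("`coeff_indices` must have one entry per watermark bit", call. = FALSE)
  nyq <- if (n %% 2L == 0L) n %/% 2L + 1L else NA_integer_
  if (anyDuplicated(coeff_indices) || any(coeff_indices <= 1L) ||
      any(coeff_indices >= n %/% 2L + 1L) ||
      (!is.na(nyq) && any(coeff_indices == nyq)))
    stop("`coeff_indices` must be distinct, exclude the DC and Nyquist bins, and lie in the first half of the spectrum",
         call. = FALSE)

  X <- stats::fft(xs)
  ref <- Mod(X[coeff_indices])
  for (j in seq_len(Lb)) {
    k <- coeff_indices[j]
    mag <- Mod(X[k])
    phase <- if (mag > 0) X[k] / mag else complex(real = 1)
    new_mag <- if (bits[j] == 1L) mag + alpha else max(mag - alpha, magnitude_floor)
    X[k] <- new_mag * phase
    if (conjugate_update == "mirror") X[n + 2L - k] <- Conj(X[k])
  }
  y <- stats::fft(X, inverse = TRUE) / n
  wm <- Re(y)
  attributes(wm) <- attributes(x)[names(attributes(x)) != "names"]
  .new_record("freq", alpha, bits, coeff_indices, reference = ref,
              watermarked = wm,
              extra = list(conjugate_update = conjugate_update,
                           imag_residue = max(abs(Im(y)))))
}

#' Extract a frequency-domain watermark
#'
#' Compares the DFT magnitude of the suspect signal at each payload bin with
#' the stored original magnitude: larger than the reference reads as bit 1,
#' otherwise bit 0.
#'
#' @param record a `wm_record` with strategy `"freq"`.
#' @param suspect the signal to test; defaults to the watermarked signal
#'   stored in the record.
#' @return recovered `watermark_bits`, with the magnitude differences
#'   attached as attribute `continuous`.
#' @export
extract_freq <- function(record, suspect = NULL) {
  if (!inherits(record, "wm_record") || record$strategy != "freq")
    stop("`record` must be a wm_record with strategy \"freq\"", call. = FALSE)
  if (is.null(suspect)) suspect <- record$watermarked
  xs <- .check_signal(suspect, "suspect")
  if (max(record$indices) > length(xs) %/% 2L)
    stop("suspect signal is shorter than the record's payload bins", call. = FALSE)
  mag <- Mod(stats::fft(xs)[record$indices])
  out <- watermark_bits(as.integer(mag > record$reference))
  attr(out, "continuous") <- mag - record$reference
  out
}

#' Serialize or restore an embed record as JSON
#'
#' Records are written as plain-text JSON sidecar files next to the signal
#' data, holding strategy, strength, payload indices, reference values and
#' the watermarked signal.
#'
#' @param record a `wm_record`.
#' @param path file path.
#' @return `write_record` returns `path` invisibly; `read_record` the record.
#' @export
write_record <- function(record, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required to serialize records", call. = FALSE)
  if (!inherits(record, "wm_record")) stop("`record` must be a wm_record",
                                           call. = FALSE)
  payload <- unclass(record)
  payload$watermarked <- as.numeric(payload$watermarked)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required to read records", call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$bits <- as.integer(raw$bits)
  raw$indices <- as.integer(raw$indices)
  structure(raw, class = "wm_record")
}
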