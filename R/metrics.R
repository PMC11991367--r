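#' Mean squared error between two signals
#'
#' `(1/N) * sum((a - b)^2)` over paired samples.
#'
#' @param a,b numeric signals of equal length.
#' @return nonnegative number.
#' @export
mse <- function(a, b) {
  a <- .check_signal(a, "a"); b <- .check_signal(b, "b")
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length", call. = FALSE)
  mean((a - b)^2)
}

#' Dynamic time warping distance
#'
#' Classic unconstrained DTW with absolute-difference local cost and anchored
#' endpoints: `D(i, j) = |a_i - b_j| + min(D(i-1, j), D(i, j-1), D(i-1, j-1))`.
#' Lengths may differ. DTW is symmetric under this step pattern but is not a
#' metric (the triangle inequality can fail).
#'
#' @param a,b non-empty numeric signals.
#' @param window optional Sakoe-Chiba band half-width: cells with
#'   `|i - j| > window` are excluded. `NULL` (default) means unconstrained.
#' @return nonnegative accumulated distance `D(n, m)`.
#' @export
dtw_distance <- function(a, b, window = NULL) {
  a <- .check_signal(a, "a"); b <- .check_signal(b, "b")
  n <- length(a); m <- length(b)
  if (!is.null(window)) {
    window <- .check_count(window, "window", lower = 0L)
    if (window < abs(n - m))
      stop("`window` is too small to connect the endpoints", call. = FALSE)
  }
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    js <- if (is.null(window)) seq_len(m) else
      max(1L, i - window):min(m, i + window)
    cost <- abs(a[i] - b[js])
    for (k in seq_along(js)) {
      j <- js[k]
      D[i + 1L, j + 1L] <- cost[k] +
        min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' Signal-to-noise ratio in decibels
#'
#' `-10 * log10(sum((s_hat - s)^2) / sum(s^2))`: the ratio of residual energy
#' to reference-signal energy, negated so that a small residual yields a
#' large positive SNR. Identical inputs return `+Inf`.
#'
#' @param s reference signal (must not be all zero).
#' @param s_hat test (e.g. watermarked) signal, same length.
#' @return SNR in dB, possibly `Inf`.
#' @export
snr_db <- function(s, s_hat) {
  s <- .check_signal(s, "s"); s_hat <- .check_signal(s_hat, "s_hat")
  if (length(s) != length(s_hat))
    stop("`s` and `s_hat` must have equal length", call. = FALSE)
  es <- sum(s^2)
  if (es == 0) stop("reference signal is all zero: SNR undefined", call. = FALSE)
  er <- sum((s_hat - s)^2)
  if (er == 0) return(Inf)
  -10 * log10(er / es)
}

#' Bit-error rate in percent
#'
#' `100 * (number of mismatched bits) / (total bits)`.
#'
#' @param w reference bits.
#' @param w_hat recovered bits, same length.
#' @return number in `[0, 100]`.
#' @export
ber_percent <- function(w, w_hat) {
  w <- .check_bits(w); w_hat <- .check_bits(w_hat)
  if (length(w) != length(w_hat))
    stop("`w` and `w_hat` must have equal length", call. = FALSE)
  100 * sum(w != w_hat) / length(w)
}

#' Combined fidelity and detection report
#'
#' @param s,s_hat reference and test signals.
#' @param w,w_hat optional reference and recovered watermark bits.
#' @return list of class `metrics_report` with `mse`, `dtw`, `snr_db` and
#'   (when bits are given) `ber_percent`.
#' @export
metrics_report <- function(s, s_hat, w = NULL, w_hat = NULL) {
  out <- list(mse = mse(s, s_hat),
              dtw = dtw_distance(s, s_hat),
              snr_db = snr_db(s, s_hat),
              ber_percent = if (!is.null(w) && !is.null(w_hat))
                ber_percent(w, w_hat) else NA_real_)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MSE %.6g | DTW %.6g | SNR %.4g dB | BER %s\n",
              x$mse, x$dtw, x$snr_db,
              if (is.na(x$ber_percent)) "-" else sprintf("%.4g%%", x$ber_percent)))
  invisible(x)
}
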