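#' Specification of one sensor filter stage
#'
#' The sensor front-end is modeled as a cascade of Butterworth stages; the
#' default chain (see [ecg_filter_chain()]) is a 1 Hz high-pass, a 10 Hz
#' low-pass and a 5-20 Hz band-pass, applied in that order.
#'
#' @param kind `"lowpass"`, `"highpass"` or `"bandpass"`.
#' @param cutoff_hz cutoff frequency in Hz (a low/high pair for bandpass).
#'   All cutoffs must lie strictly below the Nyquist frequency.
#' @param order Butterworth order (per band edge for bandpass).
#' @param sample_rate sampling rate of the signals the stage will filter.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass", "bandpass"),
                        cutoff_hz, order = 2L, sample_rate = 250) {
  kind <- match.arg(kind)
  order <- .check_count(order, "order", lower = 1L)
  .check_number(sample_rate, "sample_rate", lower = 1e-9)
  nyq <- sample_rate / 2
  if (kind == "bandpass") {
    if (length(cutoff_hz) != 2L || !is.numeric(cutoff_hz))
      stop("bandpass needs a low/high cutoff pair", call. = FALSE)
    if (cutoff_hz[1] <= 0 || cutoff_hz[1] >= cutoff_hz[2])
      stop("bandpass cutoffs must satisfy 0 < low < high", call. = FALSE)
    if (cutoff_hz[2] >= nyq)
      stop("cutoffs must lie strictly below the Nyquist frequency", call. = FALSE)
  } else {
    if (length(cutoff_hz) != 1L || !is.numeric(cutoff_hz) || cutoff_hz <= 0)
      stop("`cutoff_hz` must be a single positive frequency", call. = FALSE)
    if (cutoff_hz >= nyq)
      stop("cutoffs must lie strictly below the Nyquist frequency", call. = FALSE)
  }
  structure(list(kind = kind, cutoff_hz = as.numeric(cutoff_hz),
                 order = order, sample_rate = sample_rate),
            class = "filter_spec")
}

#' Default ECG sensor conditioning chain
#'
#' @param sample_rate sampling rate in Hz.
#' @param order Butterworth order per stage.
#' @return list of [filter_spec()] stages: 1 Hz high-pass, 10 Hz low-pass,
#'   5-20 Hz band-pass.
#' @export
ecg_filter_chain <- function(sample_rate = 250, order = 2L) {
  list(filter_spec("highpass", 1.0, order, sample_rate),
       filter_spec("lowpass", 10.0, order, sample_rate),
       filter_spec("bandpass", c(5.0, 20.0), order, sample_rate))
}

#' Design the digital Butterworth filter for a stage
#'
#' Bilinear-transform Butterworth design at the stage's sample rate. The
#' returned filter is checked for stability (all poles strictly inside the
#' unit circle).
#'
#' @param spec a [filter_spec()].
#' @return list with numerator `b`, denominator `a` and the `spec`.
#' @export
design_filter <- function(spec) {
  if (!inherits(spec, "filter_spec"))
    stop("`spec` must be a filter_spec", call. = FALSE)
  W <- spec$cutoff_hz / (spec$sample_rate / 2)
  type <- switch(spec$kind, lowpass = "low", highpass = "high",
                 bandpass = "pass")
  flt <- signal::butter(spec$order, W, type = type)
  a <- as.numeric(flt$a); b <- as.numeric(flt$b)
  poles <- polyroot(rev(a))
  if (any(Mod(poles) >= 1 - 1e-12))
    stop("designed filter is unstable; reduce the order or move the cutoffs",
         call. = FALSE)
  list(b = b, a = a, spec = spec)
}

#' Apply a filter chain to a signal
#'
#' Cascade application of the stages in order. By default the stages run
#' causally, as a physical sensor chain would; `zero_phase = TRUE` uses
#' forward-backward filtering instead.
#'
#' @param x the input signal. If it carries a `sampling_rate` attribute it
#'   must match the stage sample rates.
#' @param specs list of [filter_spec()] stages (may be empty: identity).
#' @param zero_phase use `signal::filtfilt` instead of causal filtering.
#' @return filtered signal, same length and attributes as the input.
#' @export
apply_chain <- function(x, specs, zero_phase = FALSE) {
  xs <- .check_signal(x, "x")
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  if (!is.list(specs))
    stop("`specs` must be a list of filter_spec stages", call. = FALSE)
  sr <- attr(x, "sampling_rate")
  out <- xs
  for (spec in specs) {
    if (!inherits(spec, "filter_spec"))
      stop("every chain element must be a filter_spec", call. = FALSE)
    if (!is.null(sr) && abs(spec$sample_rate - sr) > 1e-9)
      stop(sprintf("signal sampling rate %g Hz does not match stage sample rate %g Hz",
                   sr, spec$sample_rate), call. = FALSE)
    flt <- design_filter(spec)
    out <- if (zero_phase)
      as.numeric(signal::filtfilt(flt$b, flt$a, out))
    else
      as.numeric(signal::filter(flt$b, flt$a, out))
  }
  attributes(out) <- attributes(x)[names(attributes(x)) != "names"]
  out
}

# H(e^{jw}) for one rational filter at angular frequencies w (rad/sample)
.freq_resp <- function(b, a, w) {
  Eb <- exp(-1i * outer(w, seq_along(b) - 1))
  Ea <- exp(-1i * outer(w, seq_along(a) - 1))
  as.vector(Eb %*% b) / as.vector(Ea %*% a)
}

# phase unwrapping: remove 2*pi jumps between adjacent points
.unwrap <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Bode response of a filter chain
#'
#' Evaluates the combined frequency response (product of stage responses) on
#' a log-spaced grid and returns magnitude in dB and unwrapped phase in
#' degrees.
#'
#' @param specs list of [filter_spec()] stages sharing one sample rate.
#' @param f_min_hz,f_max_hz frequency range, `0 < f_min < f_max < Nyquist`.
#' @param n_points number of log-spaced grid points.
#' @return data frame of class `frequency_response` with columns
#'   `frequency_hz`, `magnitude_db`, `phase_deg`.
#' @export
bode_response <- function(specs, f_min_hz = 0.1, f_max_hz = 100,
                          n_points = 256L) {
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("`specs` must hold at least one stage",
                                call. = FALSE)
  n_points <- .check_count(n_points, "n_points", lower = 2L)
  sr <- specs[[1]]$sample_rate
  for (spec in specs)
    if (abs(spec$sample_rate - sr) > 1e-9)
      stop("all stages must share one sample rate", call. = FALSE)
  .check_number(f_min_hz, "f_min_hz", lower = 1e-12)
  .check_number(f_max_hz, "f_max_hz")
  if (f_min_hz >= f_max_hz || f_max_hz >= sr / 2)
    stop("need 0 < f_min_hz < f_max_hz < Nyquist", call. = FALSE)
  f <- exp(seq(log(f_min_hz), log(f_max_hz), length.out = n_points))
  w <- 2 * pi * f / sr
  H <- rep(1 + 0i, n_points)
  for (spec in specs) {
    flt <- design_filter(spec)
    H <- H * .freq_resp(flt$b, flt$a, w)
  }
  out <- data.frame(frequency_hz = f,
                    magnitude_db = 20 * log10(Mod(H)),
                    phase_deg = .unwrap(Arg(H)) * 180 / pi)
  class(out) <- c("frequency_response", "data.frame")
  out
}
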