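#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels, the
#' standard spatial filter for removing globally coherent background activity
#' before analyzing slow cortical potentials. The output has zero column mean
#' by construction and the operation is idempotent.
#'
#' @param signal Numeric matrix, channels x samples (at least 2 channels).
#' @return Matrix of the same shape with zero cross-channel mean per sample.
#' @export
apply_car <- function(signal) {
  if (!is.matrix(signal) || nrow(signal) < 2L)
    stop("common average reference needs a matrix with >= 2 channels")
  sweep(signal, 2L, colMeans(signal), "-")
}

#' Zero-phase Butterworth filter specification
#'
#' @param kind `"lowpass"`, `"highpass"` or `"bandpass"`.
#' @param cutoffs Cutoff frequency in Hz (two values for band-pass).
#' @param order Butterworth order of the single-pass design (the
#'   forward-backward application squares the magnitude response, doubling
#'   the effective order).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass", "bandpass"),
                        cutoffs, order = 2L) {
  kind <- match.arg(kind)
  cutoffs <- sort(as.numeric(cutoffs))
  if (kind == "bandpass" && length(cutoffs) != 2L)
    stop("bandpass needs two cutoffs")
  if (kind != "bandpass" && length(cutoffs) != 1L)
    stop(kind, " needs one cutoff")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  if (order < 1L) stop("order must be >= 1")
  structure(list(kind = kind, cutoffs = cutoffs, order = as.integer(order)),
            class = "filter_spec")
}

butter_of <- function(spec, rate) {
  ny <- rate / 2
  if (any(spec$cutoffs >= ny))
    stop("cutoff(s) must be strictly below the Nyquist frequency ", ny, " Hz")
  w <- spec$cutoffs / ny
  switch(spec$kind,
         lowpass = signal::butter(spec$order, w, type = "low"),
         highpass = signal::butter(spec$order, w, type = "high"),
         bandpass = signal::butter(spec$order, w, type = "pass"))
}

filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  # odd (anti-symmetric) reflection about both endpoints tames edge
  # transients, which for slow-cortical-potential bands last seconds
  head_pad <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(signal::Arma(b = b, a = a), c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

apply_filtfilt <- function(flt, signal, rate, order) {
  one_channel <- is.null(dim(signal))
  if (one_channel) signal <- matrix(signal, nrow = 1L)
  if (ncol(signal) <= 3L * (2L * order + 1L))
    stop("signal too short for zero-phase filtering at this order")
  pad <- as.integer(max(3L * 2L * order, round(3 * rate)))
  out <- t(apply(signal, 1L, function(x)
    filtfilt_padded(flt$b, flt$a, x, pad)))
  if (one_channel) out[1L, ] else out
}

#' Zero-phase (forward-backward) Butterworth filtering
#'
#' Designs a Butterworth filter from `spec` and applies it forward and
#' backward per channel, so the net group delay is zero and the effective
#' magnitude response is the squared single-pass response. The signal is
#' reflect-padded (odd symmetry, `max(6 x order, 3 s)` samples) before
#' filtering to suppress edge transients, which for sub-hertz bands last
#' seconds. If the direct band-pass design is
#' numerically unstable at the requested corner frequencies, a warning is
#' emitted and an equivalent high-pass + low-pass cascade is used instead.
#'
#' @param signal Numeric matrix (channels x samples) or vector.
#' @param spec A [filter_spec()].
#' @param rate Sampling rate in Hz.
#' @return Filtered signal, same shape as the input.
#' @export
zero_phase_filter <- function(signal, spec, rate) {
  stopifnot(inherits(spec, "filter_spec"))
  flt <- butter_of(spec, rate)
  out <- apply_filtfilt(flt, signal, rate, spec$order)
  if (all(is.finite(out))) return(out)
  if (spec$kind != "bandpass")
    stop("unstable filter design: kind=", spec$kind,
         " cutoffs=", paste(spec$cutoffs, collapse = "-"), " Hz @ ", rate,
         " Hz")
  warning("band-pass design unstable; falling back to high-pass + low-pass ",
          "cascade")
  hp <- butter_of(filter_spec("highpass", spec$cutoffs[1L], spec$order), rate)
  lp <- butter_of(filter_spec("lowpass", spec$cutoffs[2L], spec$order), rate)
  out <- apply_filtfilt(hp, signal, rate, spec$order)
  apply_filtfilt(lp, out, rate, spec$order)
}

#' Integer-factor resampling
#'
#' Decimates by an integer factor after zero-phase anti-alias low-pass
#' filtering (Butterworth order 4 at 0.45 of the output Nyquist-doubled rate,
#' i.e. 0.9 of the output Nyquist). Kept samples are anchored at the first
#' sample, so the output length is `floor(n * rate_out / rate_in)` whenever
#' `rate_in` divides `n`.
#'
#' @param signal Matrix (channels x samples) or vector.
#' @param rate_in,rate_out Input and output rates in Hz; `rate_in` must be an
#'   integer multiple of `rate_out`.
#' @param antialias Apply the anti-alias low-pass (default `TRUE`). Set to
#'   `FALSE` when the signal is already band-limited below the output
#'   Nyquist, e.g. after the 120 Hz low-pass of the standard chain.
#' @return Resampled signal.
#' @export
resample_signal <- function(signal, rate_in, rate_out, antialias = TRUE) {
  q <- rate_in / rate_out
  if (abs(q - round(q)) > 1e-9)
    stop("rate_in must be an integer multiple of rate_out (got factor ", q,
         ")")
  q <- as.integer(round(q))
  if (q == 1L) return(signal)
  if (antialias)
    signal <- zero_phase_filter(signal,
                                filter_spec("lowpass", 0.45 * rate_out, 4L),
                                rate_in)
  idx <- function(n) seq.int(1L, n - (n %% q), by = q)
  if (is.null(dim(signal))) signal[idx(length(signal))]
  else signal[, idx(ncol(signal)), drop = FALSE]
}

#' Resample a recording, remapping event sample indices
#'
#' @param rec An [recording()].
#' @param rate_out Target rate; the current rate must be an integer multiple.
#' @param antialias Passed to [resample_signal()].
#' @return An [recording()] at `rate_out` with event samples divided by the
#'   decimation factor.
#' @export
resample_recording <- function(rec, rate_out, antialias = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate == rate_out) return(rec)
  q <- as.integer(round(rec$rate / rate_out))
  sig <- resample_signal(rec$signal, rec$rate, rate_out, antialias)
  ev <- rec$events
  if (nrow(ev)) ev$sample <- ev$sample %/% q
  recording(sig, rate_out, rec$channel_labels, ev)
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation of the analytic extension of a real signal: the
#' negative-frequency half of the spectrum is zeroed and the positive half
#' doubled. The modulus of the result is the instantaneous amplitude
#' (envelope) and its argument the instantaneous phase of a narrow-band
#' signal.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}
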