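#' Frequency-band specification
#'
#' A band couples a pass-band in Hz with the feature representation extracted
#' from it. Slow bands (high edge <= 7 Hz) use the band-passed amplitude
#' directly; faster bands use the Hilbert envelope (instantaneous amplitude)
#' or the instantaneous phase, since raw oscillatory amplitude at those
#' frequencies is not phase-locked to movement onset. Requesting amplitude
#' above 7 Hz or envelope/phase below 7 Hz is allowed but flagged with a
#' warning.
#'
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 <= low < high`.
#' @param feature_mode `"amplitude"`, `"envelope"` or `"phase"`.
#' @param order Butterworth order of the band filter (single pass).
#' @return A `band_spec` object.
#' @export
band_spec <- function(name, low, high,
                      feature_mode = c("amplitude", "envelope", "phase"),
                      order = 2L) {
  feature_mode <- match.arg(feature_mode)
  if (!(low >= 0 && low < high)) stop("need 0 <= low < high")
  if (feature_mode == "amplitude" && high > 7)
    warning("amplitude features above 7 Hz are unconventional for this ",
            "pipeline; envelope is the standard choice")
  if (feature_mode != "amplitude" && low < 7)
    warning(feature_mode, " features below 7 Hz are unconventional for ",
            "this pipeline; amplitude is the standard choice")
  structure(list(name = name, low = low, high = high,
                 feature_mode = feature_mode, order = as.integer(order)),
            class = "band_spec")
}

#' Default analysis bands
#'
#' The standard band set: SCP 0.1-1 Hz, delta 1-4 Hz and theta 4-8 Hz as
#' amplitude features; alpha 7-13 Hz, beta 13-20 Hz, high-beta 20-30 Hz and
#' low-gamma 30-45 Hz as Hilbert-envelope features. `phase = TRUE` returns
#' the parallel instantaneous-phase set for the >= 7 Hz bands.
#'
#' @param phase Return the phase-feature variant of the fast bands.
#' @return Named list of [band_spec()]s.
#' @export
default_bands <- function(phase = FALSE) {
  defs <- list(
    scp = c(0.1, 1), delta = c(1, 4), theta = c(4, 8),
    alpha = c(7, 13), beta = c(13, 20), high_beta = c(20, 30),
    low_gamma = c(30, 45)
  )
  out <- lapply(names(defs), function(nm) {
    lo <- defs[[nm]][1]; hi <- defs[[nm]][2]
    if (hi <= 8 && !phase) {
      # theta's 8 Hz edge keeps the amplitude convention of the slow bands
      suppressWarnings(band_spec(nm, lo, hi, "amplitude"))
    } else if (phase) {
      if (lo < 7) return(NULL)
      band_spec(paste0(nm, "_phase"), lo, hi, "phase")
    } else {
      band_spec(nm, lo, hi, "envelope")
    }
  })
  names(out) <- vapply(out, function(b) if (is.null(b)) "" else b$name, "")
  out[!vapply(out, is.null, TRUE)]
}

#' Band-limited feature signal
#'
#' Band-pass filters the signal (zero-phase Butterworth) and derives the
#' requested representation: `amplitude` keeps the band-passed signal,
#' `envelope` takes the modulus of its analytic signal, `phase` its argument
#' in (-pi, pi]. The transform is applied per channel over the continuous
#' signal; epoch afterwards so that epoch edges carry no Hilbert edge
#' distortion. `envelope_mode = "rectified"` substitutes the rectified
#' band-passed signal (absolute value of the real part of the analytic
#' signal) for the modulus envelope.
#'
#' @param signal Matrix (channels x samples) or vector.
#' @param band A [band_spec()].
#' @param rate Sampling rate in Hz.
#' @param envelope_mode `"modulus"` (default) or `"rectified"`.
#' @return A `band_signal`: list with `band`, `signal`, `rate`,
#'   `representation`.
#' @export
band_features <- function(signal, band, rate,
                          envelope_mode = c("modulus", "rectified")) {
  stopifnot(inherits(band, "band_spec"))
  envelope_mode <- match.arg(envelope_mode)
  spec <- if (band$low <= 0)
    filter_spec("lowpass", band$high, band$order)
  else
    filter_spec("bandpass", c(band$low, band$high), band$order)
  filtered <- zero_phase_filter(signal, spec, rate)
  one_channel <- is.null(dim(filtered))
  if (one_channel) filtered <- matrix(filtered, nrow = 1L)
  out <- switch(band$feature_mode,
    amplitude = filtered,
    envelope = {
      if (envelope_mode == "rectified") abs(filtered)
      else t(apply(filtered, 1L, function(x) Mod(analytic_signal(x))))
    },
    phase = {
      if (band$high - band$low > band$low)
        warning("band wider than its low edge: instantaneous phase may be ",
                "ill-defined")
      t(apply(filtered, 1L, function(x) Arg(analytic_signal(x))))
    })
  if (one_channel) out <- out[1L, , drop = FALSE]
  structure(list(band = band, signal = out, rate = rate,
                 representation = band$feature_mode),
            class = "band_signal")
}

#' Band-limited feature signal from a recording
#'
#' Convenience wrapper around [band_features()] keeping channel labels and
#' events alongside the transformed signal.
#'
#' @param rec A (preprocessed) [recording()].
#' @param band A [band_spec()].
#' @param ... Passed to [band_features()].
#' @return A `band_signal` with `channel_labels` and `events` attached.
#' @export
band_signal_of <- function(rec, band, ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  bs <- band_features(rec$signal, band, rec$rate, ...)
  bs$channel_labels <- rec$channel_labels
  bs$events <- rec$events
  bs
}
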