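#' Epoch a band signal around trial events
#'
#' Cuts one segment per trial, aligned to the movement onset (intention
#' period) or the target cue (idle period). The span `(start, end]` is
#' half-open: a span of \[-2, 1\] s at 128 Hz yields 384 samples, the first at
#' `start + 1/rate` and the last exactly at `end`, matching the convention
#' that windows are labeled by their endpoint. Trials whose span does not
#' fit inside the recording are dropped with a message. Trials are returned
#' in chronological order.
#'
#' @param bs A `band_signal` from [band_signal_of()] (carries events).
#' @param alignment `"onset"` or `"cue"`.
#' @param span Length-2 numeric, seconds relative to the alignment event.
#' @param events Optional event table overriding the one in `bs`.
#' @return An `epoch_set`: `data` (trials x channels x samples array),
#'   `rate`, `span`, `alignment`, `labels` (directions), `trial_ids`,
#'   `channel_labels`.
#' @export
epoch_band <- function(bs, alignment = c("onset", "cue"), span,
                       events = NULL) {
  stopifnot(inherits(bs, "band_signal"))
  alignment <- match.arg(alignment)
  if (is.null(events)) events <- bs$events
  if (is.null(events)) stop("no events available for epoching")
  ev <- events[events$kind == alignment & !is.na(events$direction), ,
               drop = FALSE]
  ev <- ev[order(ev$sample), , drop = FALSE]
  if (!nrow(ev)) stop("no ", alignment, " events to epoch around")
  rate <- bs$rate
  n <- ncol(bs$signal)
  rel <- seq.int(as.integer(round(span[1] * rate)) + 1L,
                 as.integer(round(span[2] * rate)))
  # event samples are 0-based; R matrix columns are 1-based
  first <- ev$sample + 1L + rel[1L]
  last <- ev$sample + 1L + rel[length(rel)]
  ok <- first >= 1L & last <= n
  if (any(!ok))
    message("dropping ", sum(!ok),
            " trial(s) whose epoch span exceeds the recording")
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) stop("no trial fits the requested span")
  n_ch <- nrow(bs$signal)
  data <- array(0, dim = c(nrow(ev), n_ch, length(rel)))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- bs$signal[, ev$sample[i] + 1L + rel, drop = FALSE]
  structure(list(
    data = data, rate = rate, span = span, alignment = alignment,
    labels = ev$direction, trial_ids = ev$trial_id,
    channel_labels = bs$channel_labels,
    representation = bs$representation
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %s-aligned (%g, %g] s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate, x$alignment,
    x$span[1], x$span[2]))
  invisible(x)
}

#' Sliding-window grid
#'
#' Window endpoints from `span[1] + window_len` to `span[2]`, spaced by
#' `step`. Every window `(endpoint - window_len, endpoint]` lies fully
#' inside the span. With the defaults over the intention span \[-2, 1\] s the
#' grid has 45 endpoints from -1.75 to 1 s. If the step does not divide the
#' residual span the last endpoint falls short of `span[2]` (with a
#' message).
#'
#' @param span Length-2 numeric span in seconds.
#' @param window_len Window length in seconds.
#' @param step Step between endpoints in seconds.
#' @return A `window_grid`: `endpoints`, `window_len`, `step`.
#' @export
make_grid <- function(span, window_len = 0.25, step = 0.0625) {
  if (diff(span) < window_len - 1e-9)
    stop("span shorter than the window length")
  m <- floor((span[2] - span[1] - window_len) / step + 1e-9)
  endpoints <- span[1] + window_len + step * (0:m)
  if (abs(endpoints[length(endpoints)] - span[2]) > 1e-9)
    message("window step does not divide the span; last endpoint at ",
            endpoints[length(endpoints)], " s < ", span[2], " s")
  structure(list(endpoints = endpoints, window_len = window_len,
                 step = step, span = span),
            class = "window_grid")
}

#' Per-window feature matrix
#'
#' Extracts, for one window endpoint, every trial's feature vector: the
#' window's samples on the requested channels, decimated to `feature_rate`
#' with the kept samples anchored at the window end (so the endpoint sample
#' is always included), flattened channel-major. With a 250 ms window,
#' 128 Hz signal and 16 Hz feature rate this gives 4 points per channel —
#' 40 features for 10 channels. For phase-representation epochs with
#' `phase_encoding = "cos_sin"` each point expands into its cosine and sine,
#' doubling the column count while removing the circular discontinuity.
#'
#' @param epochs An [epoch_band()] result.
#' @param endpoint Window endpoint in seconds relative to the alignment
#'   event; the window is `(endpoint - window_len, endpoint]`.
#' @param window_len Window length in seconds.
#' @param channels Channels to include (default all epoch channels).
#' @param feature_rate Feature sampling rate in Hz; must divide the epoch
#'   rate.
#' @param phase_encoding `"cos_sin"` or `"raw_angle"`; used only for phase
#'   epochs.
#' @return A `window_features` object: `x` (trials x features matrix),
#'   `provenance` (per column: channel, within-window time, component),
#'   `labels`, `trial_ids`, `endpoint`.
#' @export
window_features <- function(epochs, endpoint, window_len = 0.25,
                            channels = NULL, feature_rate = 16,
                            phase_encoding = c("cos_sin", "raw_angle")) {
  stopifnot(inherits(epochs, "epoch_set"))
  phase_encoding <- match.arg(phase_encoding)
  rate <- epochs$rate
  dec <- rate / feature_rate
  if (abs(dec - round(dec)) > 1e-9)
    stop("feature_rate must divide the epoch rate")
  dec <- as.integer(round(dec))
  if (is.null(channels)) channels <- epochs$channel_labels
  ch_idx <- match(channels, epochs$channel_labels)
  if (anyNA(ch_idx))
    stop("channels not in the epoch set: ",
         paste(channels[is.na(ch_idx)], collapse = ", "))
  npts <- as.integer(round(window_len * feature_rate))
  end_idx <- as.integer(round((endpoint - epochs$span[1]) * rate))
  idx <- end_idx - dec * ((npts - 1L):0L)
  if (idx[1L] < 1L || end_idx > dim(epochs$data)[3])
    stop("window (", endpoint - window_len, ", ", endpoint,
         "] s falls outside the epoch span")
  n_tr <- dim(epochs$data)[1]
  block <- epochs$data[, ch_idx, idx, drop = FALSE]       # trials x C x P
  x <- aperm(block, c(1L, 3L, 2L))                        # trials x P x C
  dim(x) <- c(n_tr, npts * length(ch_idx))                # channel-major
  times <- endpoint - ((npts - 1L):0L) / feature_rate
  prov <- data.frame(
    channel = rep(channels, each = npts),
    time = rep(times, times = length(channels)),
    component = "value", stringsAsFactors = FALSE)
  if (identical(epochs$representation, "phase") &&
      phase_encoding == "cos_sin") {
    p <- ncol(x)
    xx <- matrix(0, n_tr, 2L * p)
    xx[, 2L * seq_len(p) - 1L] <- cos(x)
    xx[, 2L * seq_len(p)] <- sin(x)
    x <- xx
    prov <- prov[rep(seq_len(p), each = 2L), , drop = FALSE]
    prov$component <- rep(c("cos", "sin"), p)
    rownames(prov) <- NULL
  }
  structure(list(x = x, provenance = prov, labels = epochs$labels,
                 trial_ids = epochs$trial_ids, endpoint = endpoint,
                 window_len = window_len, feature_rate = feature_rate),
            class = "window_features")
}
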