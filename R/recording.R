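#' Continuous multichannel EEG recording
#'
#' An `eeg_recording` bundles a channels-by-samples signal matrix (microvolts),
#' its sampling rate, electrode labels and an event table. Events mark the
#' target cue and the movement onset of each center-out trial, with the
#' reached direction as the class label. Sample indices are 0-based so that
#' `sample / rate` is the time of the sample since recording start.
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector of unique 10/20 electrode names,
#'   one per signal row.
#' @param events Data frame with columns `trial_id` (integer), `kind`
#'   (`"cue"` or `"onset"`), `sample` (0-based integer index) and `direction`
#'   (`"up"`, `"down"`, `"left"`, `"right"`, or `NA` for non-trial events).
#'   May be `NULL` for an event-free recording.
#' @return An object of class `eeg_recording`.
#' @seealso [select_channels()], [write_recording()], [generate_recording()]
#' @export
recording <- function(signal, rate, channel_labels, events = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  if (length(channel_labels) != nrow(signal))
    stop("length(channel_labels) must equal nrow(signal)")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  events <- normalize_events(events, n_samples = ncol(signal))
  structure(
    list(signal = signal, rate = rate,
         channel_labels = as.character(channel_labels), events = events),
    class = "eeg_recording"
  )
}

empty_events <- function() {
  data.frame(trial_id = integer(), kind = character(),
             sample = integer(), direction = character(),
             stringsAsFactors = FALSE)
}

normalize_events <- function(events, n_samples) {
  if (is.null(events) || nrow(events) == 0L) return(empty_events())
  req <- c("trial_id", "kind", "sample", "direction")
  if (!all(req %in% names(events)))
    stop("events must have columns: ", paste(req, collapse = ", "))
  events <- events[req]
  if (!all(events$kind %in% c("cue", "onset")))
    stop("event kind must be 'cue' or 'onset'")
  dirs <- events$direction
  if (!all(is.na(dirs) | dirs %in% direction_labels()))
    stop("event direction must be one of ",
         paste(direction_labels(), collapse = "/"), " or NA")
  if (any(events$sample < 0L | events$sample >= n_samples))
    stop("event sample indices must lie in [0, n_samples)")
  events <- events[order(events$sample, events$trial_id), , drop = FALSE]
  rownames(events) <- NULL
  events$trial_id <- as.integer(events$trial_id)
  events$sample <- as.integer(events$sample)
  events
}

#' The four center-out target directions
#' @return `c("up", "down", "left", "right")`.
#' @export
direction_labels <- function() c("up", "down", "left", "right")

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate,
    nrow(x$events)))
  invisible(x)
}

#' Paired cue/onset events per trial
#'
#' Returns one row per trial that has both a cue and an onset event, with the
#' cue-to-onset latency in seconds. Trials with an onset but no cue are an
#' error (orphan onset); trials with a cue but no onset (e.g. aborted) are
#' dropped.
#'
#' @param rec An [recording()].
#' @return Data frame with columns `trial_id`, `direction`, `cue_sample`,
#'   `onset_sample`, `latency` (s), ordered by onset sample.
#' @export
trial_table <- function(rec) {
  ev <- rec$events
  cues <- ev[ev$kind == "cue", ]
  onsets <- ev[ev$kind == "onset", ]
  orphan <- setdiff(onsets$trial_id, cues$trial_id)
  if (length(orphan))
    stop("onset events without a matching cue for trial(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  keep <- onsets$trial_id %in% cues$trial_id
  onsets <- onsets[keep, ]
  idx <- match(onsets$trial_id, cues$trial_id)
  out <- data.frame(
    trial_id = onsets$trial_id,
    direction = onsets$direction,
    cue_sample = cues$sample[idx],
    onset_sample = onsets$sample,
    stringsAsFactors = FALSE
  )
  if (any(out$onset_sample <= out$cue_sample))
    stop("each onset must come after its trial's cue")
  out$latency <- (out$onset_sample - out$cue_sample) / rec$rate
  out <- out[order(out$onset_sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a recording to a channel subset
#'
#' Projects the recording onto the named channels, in the order of `subset`.
#' Events are unchanged. Applying the same subset twice is a no-op.
#'
#' @param rec An [recording()].
#' @param subset Character vector of channel names, all present in `rec`.
#' @return An [recording()] with `length(subset)` channels.
#' @export
select_channels <- function(rec, subset) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(subset, rec$channel_labels)
  if (length(missing))
    stop("unknown channel name(s): ", paste(missing, collapse = ", "))
  idx <- match(subset, rec$channel_labels)
  recording(rec$signal[idx, , drop = FALSE], rec$rate,
            rec$channel_labels[idx], rec$events)
}
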