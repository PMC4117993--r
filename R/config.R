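#' Decoding-pipeline configuration
#'
#' Collects every tunable of the decoding chain with the standard defaults:
#' 34-channel analysis subset, 250 ms windows sliding every 62.5 ms, an
#' intention (analysis) span of \[-2, 1\] s around movement onset and an idle
#' span of \[-1, 2\] s around the target cue, 16 Hz feature subsampling
#' (4 points per window), 10 CVA-selected channels (40 features), 5-fold
#' chronological cross-validation, 10 permutation repetitions for the chance
#' level, and a detection rule of 5 consecutive windows at p < 0.05.
#'
#' @param channel_subset Channels used for analysis (default the 34-name
#'   [default_channel_subset()]).
#' @param window_len Sliding-window length in s.
#' @param window_step Window step in s.
#' @param analysis_span Intention-period span in s relative to movement onset.
#' @param idle_span Idle-period span in s relative to the target cue.
#' @param feature_rate Feature subsampling rate in Hz; `window_len` and
#'   `window_step` must be integer multiples of `1/feature_rate`.
#' @param n_select_channels Channels retained by CVA selection.
#' @param n_folds Cross-validation folds.
#' @param n_permutation_reps Label-permutation repetitions for the chance
#'   level.
#' @param alpha Significance level of the early-detection rank-sum test.
#' @param consecutive_windows Consecutive significant windows required for
#'   detection.
#' @param proc_rate Processing rate in Hz the recording is decimated to
#'   before band filtering.
#' @param shrinkage LDA pooled-covariance shrinkage toward scaled identity.
#' @param cva_ridge Initial ridge factor regularizing the within-class
#'   scatter (escalated tenfold until well-conditioned).
#' @param cva_mode `"stacked"` (CVA on all channels x points columns) or
#'   `"channel_mean"` (CVA on per-channel within-window means).
#' @param chance_mode `"full"` (permutations re-run CVA selection) or
#'   `"refit"` (permutations reuse the unpermuted selection, refitting only
#'   the classifier).
#' @param phase_encoding `"cos_sin"` (each phase feature expands to its
#'   cosine and sine) or `"raw_angle"`.
#' @param rng_seed Master seed; permutation streams derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(channel_subset = default_channel_subset(),
                            window_len = 0.25,
                            window_step = 0.0625,
                            analysis_span = c(-2, 1),
                            idle_span = c(-1, 2),
                            feature_rate = 16,
                            n_select_channels = 10L,
                            n_folds = 5L,
                            n_permutation_reps = 10L,
                            alpha = 0.05,
                            consecutive_windows = 5L,
                            proc_rate = 128,
                            shrinkage = 0.05,
                            cva_ridge = 1e-6,
                            cva_mode = c("stacked", "channel_mean"),
                            chance_mode = c("full", "refit"),
                            phase_encoding = c("cos_sin", "raw_angle"),
                            rng_seed = 1L) {
  near_int <- function(x) abs(x - round(x)) < 1e-9
  if (!near_int(window_len * feature_rate))
    stop("window_len must be a multiple of 1/feature_rate")
  if (!near_int(window_step * feature_rate))
    stop("window_step must be a multiple of 1/feature_rate")
  if (n_select_channels > length(channel_subset))
    stop("n_select_channels exceeds the channel subset size")
  structure(list(
    channel_subset = channel_subset,
    window_len = window_len, window_step = window_step,
    analysis_span = analysis_span, idle_span = idle_span,
    feature_rate = feature_rate,
    n_select_channels = as.integer(n_select_channels),
    n_folds = as.integer(n_folds),
    n_permutation_reps = as.integer(n_permutation_reps),
    alpha = alpha, consecutive_windows = as.integer(consecutive_windows),
    proc_rate = proc_rate, shrinkage = shrinkage, cva_ridge = cva_ridge,
    cva_mode = match.arg(cva_mode), chance_mode = match.arg(chance_mode),
    phase_encoding = match.arg(phase_encoding),
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' Standard preprocessing chain
#'
#' Restricts the recording to the configured channel subset, applies the
#' common average reference, low-pass filters at 120 Hz (zero-phase
#' Butterworth, order 4; skipped when 120 Hz is not below the Nyquist
#' frequency), and decimates to `proc_rate`. Band-specific filtering comes
#' afterwards via [band_signal_of()].
#'
#' @param rec Raw [recording()].
#' @param cfg A [pipeline_config()].
#' @return Preprocessed [recording()] at `cfg$proc_rate`.
#' @export
preprocess_recording <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  subset <- intersect(cfg$channel_subset, rec$channel_labels)
  if (length(subset) < length(cfg$channel_subset))
    warning("channel subset reduced to the ", length(subset),
            " channels present in the recording")
  rec <- select_channels(rec, subset)
  rec$signal <- apply_car(rec$signal)
  if (rec$rate / 2 > 120)
    rec$signal <- zero_phase_filter(rec$signal,
                                    filter_spec("lowpass", 120, 4L),
                                    rec$rate)
  # the 120 Hz low-pass leaves content above the 64 Hz Nyquist of the
  # 128 Hz processing rate, so the decimation's own anti-alias stays on
  resample_recording(rec, cfg$proc_rate, antialias = TRUE)
}
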