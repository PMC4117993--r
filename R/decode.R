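#' End-to-end direction decoding of one recording
#'
#' Convenience driver for the full analysis of a single recording and band:
#' discard early starts, preprocess, band-filter, epoch the intention
#' (onset-aligned) and idle (cue-aligned) periods, run time-specific
#' cross-validated decoding with its permutation chance level, test for
#' early detection, select the best pre-onset window, and score the
#' selected classifier across both periods (sensitivity and specificity).
#'
#' @param rec Raw [recording()] with cue/onset events.
#' @param cfg A [pipeline_config()].
#' @param band A [band_spec()]; default the 0.1-1 Hz slow-cortical-potential
#'   band with amplitude features.
#' @return A `direction_decoding` list: `time_specific`, `chance`,
#'   `detection`, `selected`, `sensitivity`, `specificity`, `band`, `cfg`.
#' @export
decode_directions <- function(rec, cfg = pipeline_config(),
                              band = band_spec("scp", 0.1, 1, "amplitude")) {
  rec <- discard_early_starts(rec)
  pre <- preprocess_recording(rec, cfg)
  bs <- band_signal_of(pre, band)
  grid <- make_grid(cfg$analysis_span, cfg$window_len, cfg$window_step)
  idle_grid <- make_grid(cfg$idle_span, cfg$window_len, cfg$window_step)
  intention <- epoch_band(bs, "onset", cfg$analysis_span)
  idle <- epoch_band(bs, "cue", cfg$idle_span)
  ts <- run_time_specific(intention, grid, cfg)
  ch <- chance_level(intention, grid, cfg, ts = ts)
  det <- early_detection(ts, ch, alpha = cfg$alpha,
                         k_consecutive = cfg$consecutive_windows)
  sel <- select_best_window(ts)
  structure(list(
    time_specific = ts, chance = ch, detection = det, selected = sel,
    sensitivity = run_selected(sel, intention, grid, cfg),
    specificity = run_selected(sel, idle, idle_grid, cfg),
    band = band, cfg = cfg
  ), class = "direction_decoding")
}

#' @export
print.direction_decoding <- function(x, ...) {
  ts <- x$time_specific
  cat("Single-trial direction decoding (", x$band$name, " band, ",
      x$band$low, "-", x$band$high, " Hz, ", x$band$feature_mode,
      " features)\n", sep = "")
  cat(sprintf("  trials: %d  folds: %d  windows: %d over [%g, %g] s\n",
              nrow(ts$fold_plan$assignments), ts$fold_plan$n_folds,
              length(ts$endpoints), min(ts$endpoints), max(ts$endpoints)))
  cat(sprintf("  chance level (10x%d permuted CV): %.3f\n",
              ts$fold_plan$n_folds, mean(x$chance$draws)))
  cat(sprintf("  peak pre-onset DA %.2f +/- %.2f at %g s\n",
              x$selected$da_mean,
              ts$da_sd[ts$endpoints == x$selected$window_endpoint],
              x$selected$window_endpoint))
  if (is.na(x$detection$time)) {
    cat("  no early detection (no run of consecutive significant windows)\n")
  } else {
    cat(sprintf("  early detection at %g s (%d consecutive windows, p < %g)\n",
                x$detection$time, x$cfg$consecutive_windows, x$cfg$alpha))
  }
  cat(sprintf("  idle-period mean DA %.3f (specificity)\n",
              mean(x$specificity$da_mean)))
  invisible(x)
}
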