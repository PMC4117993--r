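#' Phase-feature decoding pipeline
#'
#' Runs the identical selection/classification/evaluation chain with
#' instantaneous-phase inputs: each band is filtered, its analytic signal's
#' phase extracted on the continuous recording (before epoching), and the
#' per-window phase samples become the feature vectors. With the default
#' `"cos_sin"` encoding each phase sample contributes its cosine and sine,
#' which removes the circular discontinuity at +/- pi from the linear
#' classifier's input; `"raw_angle"` feeds the wrapped angle directly for
#' literal replication. Phase features are invariant to global amplitude
#' scaling of the recording.
#'
#' @param rec Raw [recording()].
#' @param bands List of [band_spec()]s; each is coerced to
#'   `feature_mode = "phase"`.
#' @param encoding `"cos_sin"` or `"raw_angle"`.
#' @param cfg A [pipeline_config()].
#' @param with_chance Also compute each band's permutation chance level.
#' @return Named list of per-band results, as in [band_comparison()].
#' @export
phase_pipeline <- function(rec, bands, encoding = c("cos_sin", "raw_angle"),
                           cfg = pipeline_config(), with_chance = FALSE) {
  encoding <- match.arg(encoding)
  cfg$phase_encoding <- encoding
  phase_bands <- lapply(bands, function(b) {
    nm <- if (grepl("_phase$", b$name)) b$name else paste0(b$name, "_phase")
    suppressWarnings(band_spec(nm, b$low, b$high, "phase", order = b$order))
  })
  band_comparison(rec, phase_bands, cfg, with_chance = with_chance)
}
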