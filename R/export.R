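#' Tab-separated exports of analysis objects
#'
#' Plain-text writers for downstream tooling and figure scripts:
#' `export_window_features()` writes one row per trial with a header of
#' `channel@time` provenance tuples (plus the direction label);
#' `export_grid()` writes the window endpoints as a one-column list;
#' `export_dp()` writes a CVA result's per-channel discriminant power as a
#' `(channel, dp)` table ordered by rank, the input for selection
#' topographies; `export_curve()` writes a decoding curve as
#' `(endpoint, da_mean, da_sd)` with optional per-window chance means and
#' detection p-values.
#'
#' @param wf A [window_features()] object.
#' @param grid A [make_grid()] object.
#' @param result A [fit_cva()] result fitted with provenance.
#' @param curve A [run_time_specific()] / [run_selected()] curve.
#' @param chance Optional matching [chance_level()].
#' @param detection Optional matching [early_detection()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name exports
NULL

#' @rdname exports
#' @export
export_window_features <- function(wf, path) {
  stopifnot(inherits(wf, "window_features"))
  hdr <- paste0(wf$provenance$channel, "@", wf$provenance$time,
                ifelse(wf$provenance$component == "value", "",
                       paste0("#", wf$provenance$component)))
  df <- as.data.frame(wf$x)
  names(df) <- hdr
  df <- cbind(trial_id = wf$trial_ids, direction = wf$labels, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
export_grid <- function(grid, path) {
  stopifnot(inherits(grid, "window_grid"))
  utils::write.table(data.frame(endpoint = grid$endpoints), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
export_dp <- function(result, path) {
  stopifnot(inherits(result, "cva_result"))
  if (is.null(result$dp_per_channel))
    stop("CVA was fitted without channel provenance")
  ord <- match(result$ranking, result$channels)
  utils::write.table(
    data.frame(channel = result$channels[ord],
               dp = unname(result$dp_per_channel[ord])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
export_curve <- function(curve, path, chance = NULL, detection = NULL) {
  stopifnot(inherits(curve, "decoding_curve"))
  df <- data.frame(endpoint = curve$endpoints, da_mean = curve$da_mean,
                   da_sd = curve$da_sd)
  if (!is.null(chance)) {
    stopifnot(inherits(chance, "chance_level"))
    df$chance_mean <- chance$chance_mean
  }
  if (!is.null(detection)) df$p_value <- detection$pvalues
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
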