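#' Electrode montages
#'
#' `biosemi64_labels()` returns the 64 electrode names of the extended 10/20
#' montage used by a 64-channel BioSemi ActiveTwo cap, in standard cap order.
#' `default_channel_subset()` returns the default 34-channel analysis subset:
#' the montage minus the outer ring (temporal, occipital and outermost
#' frontal/parietal positions) and the frontopolar/anterior-frontal rows,
#' which are the positions most contaminated by ocular and muscular activity.
#' Real-data users should override the subset through
#' [pipeline_config()]`$channel_subset` to match their own EOG-based
#' channel exclusion.
#'
#' @return Character vector of electrode names.
#' @export
biosemi64_labels <- function() {
  c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7",
    "FC5", "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7",
    "CP5", "CP3", "CP1", "P1", "P3", "P5", "P7", "P9",
    "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz",
    "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4", "CP2",
    "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
}

#' @rdname biosemi64_labels
#' @export
default_channel_subset <- function() {
  excluded <- c(
    # frontopolar and anterior-frontal rows
    "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    # outer ring
    "F7", "F8", "FT7", "FT8", "T7", "T8", "TP7", "TP8",
    "P7", "P8", "P9", "P10", "PO7", "PO8", "O1", "Oz", "O2", "Iz",
    # outermost of the remaining frontal / parietal rows
    "F5", "F6", "P5", "P6"
  )
  full <- biosemi64_labels()
  full[!full %in% excluded]
}
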