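#' Write a recording to the internal container
#'
#' The internal container is a versioned RDS file holding a named list:
#' `version` (integer, currently 1), `signal` (channels x samples double
#' matrix, microvolts), `rate` (Hz), `channel_labels`, and `events` (the
#' tabular event set: `trial_id`, `kind`, `sample`, `direction`). RDS
#' serialization is deterministic, so writing the same recording twice gives
#' byte-identical files, and doubles round-trip at full precision.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()], [export_events()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  obj <- list(version = 1L, signal = rec$signal, rate = rec$rate,
              channel_labels = rec$channel_labels, events = rec$events)
  saveRDS(obj, path, version = 2L, compress = FALSE)
  invisible(path)
}

#' Read a recording
#'
#' Reads the internal container written by [write_recording()], or an EDF /
#' BDF (BioSemi 24-bit) file. For EDF/BDF, trial events are read from a
#' sidecar tab-separated table (`<path>.events.tsv` or `events_path`) with
#' columns `trial_id`, `kind`, `sample`, `direction`; physical units are
#' converted to microvolts using the per-signal physical dimension (`uV` or
#' `mV`).
#'
#' @param path Input file path.
#' @param format One of `"internal"`, `"edf"`, `"bdf"`.
#' @param events_path Optional sidecar event table path (EDF/BDF only).
#' @return An [recording()] with events sorted by sample index.
#' @export
read_recording <- function(path, format = c("internal", "edf", "bdf"),
                           events_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "internal") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$version) || obj$version != 1L)
      stop("not a version-1 internal recording container: ", path)
    return(recording(obj$signal, obj$rate, obj$channel_labels, obj$events))
  }
  read_edf(path, bits = if (format == "bdf") 24L else 16L,
           events_path = events_path)
}

#' Export the event table as TSV
#'
#' Writes `trial_id`, `kind`, `sample`, `direction` as a tab-separated table,
#' the sidecar format accepted by [read_recording()] for EDF/BDF input.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_events <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_events_tsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(trial_id = "integer",
                                         kind = "character",
                                         sample = "integer",
                                         direction = "character"))
  ev
}

# Minimal EDF / BDF reader. Layout: 256-byte fixed-width ASCII header, then
# 256 bytes per signal of per-signal header fields, then data records of
# interleaved per-signal sample blocks, little-endian 2's-complement integers
# (16-bit for EDF, 24-bit for BDF). Annotation streams are not parsed; events
# come from the sidecar table.
read_edf <- function(path, bits = 16L, events_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_field <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw[raw != as.raw(0)]))
  }
  hdr_field(8L)                      # version
  hdr_field(80L); hdr_field(80L)     # patient / recording id
  hdr_field(8L); hdr_field(8L)       # start date / time
  header_bytes <- as.integer(hdr_field(8L))
  hdr_field(44L)                     # reserved
  n_records <- as.integer(hdr_field(8L))
  record_dur <- as.numeric(hdr_field(8L))
  ns <- as.integer(hdr_field(4L))
  if (is.na(ns) || ns < 1L) stop("cannot parse EDF/BDF header of ", path)
  per <- function(n) vapply(seq_len(ns), function(i) hdr_field(n), "")
  labels <- per(16L)
  per(80L)                           # transducer
  dims <- per(8L)                    # physical dimension
  phys_min <- as.numeric(per(8L)); phys_max <- as.numeric(per(8L))
  dig_min <- as.numeric(per(8L));  dig_max <- as.numeric(per(8L))
  per(80L)                           # prefiltering
  nr <- as.integer(per(8L))          # samples per record per signal
  per(32L)                           # reserved
  stopifnot(seek(con, where = NA) == header_bytes)

  bytes_per <- bits %/% 8L
  raw_all <- readBin(con, "raw", n_records * sum(nr) * bytes_per)
  decode <- function(raw) {
    if (bits == 16L) {
      readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
              endian = "little", signed = TRUE)
    } else {
      m <- matrix(as.integer(raw), nrow = 3L)
      v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
      ifelse(v >= 8388608L, v - 16777216L, v)
    }
  }
  sig <- matrix(0, nrow = ns, ncol = n_records * max(nr))
  offs <- c(0L, cumsum(nr)) * bytes_per
  rec_bytes <- sum(nr) * bytes_per
  for (r in seq_len(n_records)) {
    base <- (r - 1L) * rec_bytes
    for (s in seq_len(ns)) {
      chunk <- raw_all[(base + offs[s] + 1L):(base + offs[s + 1L])]
      sig[s, ((r - 1L) * nr[s] + 1L):(r * nr[s])] <- decode(chunk)
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  unit <- ifelse(grepl("mV", dims, ignore.case = TRUE), 1000,
                 ifelse(dims == "" | grepl("uV|µV", dims), 1, NA))
  if (anyNA(unit))
    stop("unsupported physical dimension(s): ",
         paste(unique(dims[is.na(unit)]), collapse = ", "))
  sig <- (sig - dig_min) * gain + phys_min
  sig <- sig * unit
  rate <- nr[1L] / record_dur
  if (any(nr != nr[1L]))
    stop("signals with heterogeneous sampling rates are not supported")

  if (is.null(events_path)) {
    cand <- paste0(path, ".events.tsv")
    events_path <- if (file.exists(cand)) cand else NULL
  }
  events <- if (!is.null(events_path)) read_events_tsv(events_path) else NULL
  recording(sig, rate, labels, events)
}
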