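test_that("recording validates its invariants", {
  sig <- matrix(rnorm(20), 2, 10)
  expect_error(recording(sig, 0, c("C3", "C4")), "positive")
  expect_error(recording(sig, 64, c("C3", "C3")), "unique")
  expect_error(recording(sig, 64, "C3"), "channel_labels")
  ev <- data.frame(trial_id = 1L, kind = "onset", sample = 10L,
                   direction = "up")
  expect_error(recording(sig, 64, c("C3", "C4"), ev), "\\[0, n_samples\\)")
  ev$sample <- 3L
  rec <- recording(sig, 64, c("C3", "C4"), ev)
  expect_s3_class(rec, "eeg_recording")
  expect_error(recording(sig, 64, c("C3", "C4"),
                         transform(ev, direction = "north")),
               "direction")
})

test_that("events are kept sorted by sample through construction and I/O", {
  sig <- matrix(0, 2, 100)
  ev <- data.frame(trial_id = c(2L, 1L, 2L, 1L),
                   kind = c("onset", "cue", "cue", "onset"),
                   sample = c(80L, 5L, 40L, 20L),
                   direction = c("left", "up", "left", "up"))
  rec <- recording(sig, 64, c("C3", "C4"), ev)
  expect_equal(rec$events$sample, c(5L, 20L, 40L, 80L))
  p <- withr::local_tempfile(fileext = ".rds")
  write_recording(rec, p)
  expect_equal(read_recording(p)$events, rec$events)
})

test_that("select_channels restricts, reorders, and is a projection", {
  full <- biosemi64_labels()
  sub <- default_channel_subset()
  expect_length(full, 64L)
  expect_length(sub, 34L)
  expect_true(all(sub %in% full))

  g <- generate_recording(quick_synth(n_trials = 4, channels = full,
                                      rate = 128))
  rec <- g$recording
  r34 <- select_channels(rec, sub)
  expect_identical(r34$channel_labels, sub)
  expect_equal(nrow(r34$signal), 34L)
  expect_identical(select_channels(r34, sub)$signal, r34$signal)
  expect_identical(r34$events, rec$events)

  one <- select_channels(rec, "Cz")
  expect_equal(dim(one$signal), c(1L, ncol(rec$signal)))
  expect_identical(select_channels(rec, full)$signal, rec$signal)
  expect_error(select_channels(rec, "Xz"), "unknown channel")
})

test_that("internal container round-trips bit-identically", {
  rec <- tiny_recording()
  p <- withr::local_tempfile(fileext = ".rds")
  write_recording(rec, p)
  back <- read_recording(p, "internal")
  expect_identical(back$signal, rec$signal)
  expect_identical(back$events, rec$events)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$rate, rec$rate)

  # a pure sinusoid survives exactly
  t <- (0:255) / 256
  sine <- rbind(sin(2 * pi * 3 * t), cos(2 * pi * 5 * t))
  r2 <- recording(sine, 256, c("Fz", "Pz"))
  p2 <- withr::local_tempfile(fileext = ".rds")
  write_recording(r2, p2)
  expect_identical(read_recording(p2)$signal, sine)
  expect_equal(nrow(read_recording(p2)$events), 0L)

  # re-writing what was read is byte-stable
  p3 <- withr::local_tempfile(fileext = ".rds")
  write_recording(back, p3)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p3, "raw", file.size(p3)))
})

test_that("event table export matches the sidecar format", {
  rec <- tiny_recording(n_trials = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  export_events(rec, p)
  ev <- scpdecode:::read_events_tsv(p)
  expect_equal(ev, rec$events)
})

test_that("a recording with n trials carries 2n trial events", {
  g <- generate_recording(quick_synth(n_trials = 12, rate = 128))
  expect_equal(nrow(g$recording$events), 24L)
  expect_equal(sum(g$recording$events$kind == "cue"), 12L)
})

# Build a minimal valid EDF (16-bit) file from the published header layout
# and check the reader recovers signal and units.
test_that("EDF reader recovers a synthetic two-channel sine file", {
  rate <- 256L
  n_rec <- 2L                      # 2 x 1 s records
  t <- (0:(rate - 1)) / rate
  # physical signal in uV, digital range mapped [-100, 100] <-> [-2048, 2047]
  ch1 <- 50 * sin(2 * pi * 5 * t)
  ch2 <- 80 * cos(2 * pi * 2 * t)
  phys_min <- -100; phys_max <- 100
  dig_min <- -2048L; dig_max <- 2047L
  to_dig <- function(x)
    as.integer(round((x - phys_min) / (phys_max - phys_min) *
                       (dig_max - dig_min) + dig_min))
  pad <- function(x, n) {
    s <- as.character(x)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  p <- withr::local_tempfile(fileext = ".edf")
  con <- file(p, "wb")
  hdr <- paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 + 2 * 256, 8), pad("", 44), pad(n_rec, 8),
                pad("1", 8), pad("2", 4))
  sig_hdr <- paste0(pad("Fz", 16), pad("Pz", 16),      # labels
                    pad("", 80), pad("", 80),          # transducer
                    pad("uV", 8), pad("uV", 8),
                    pad(phys_min, 8), pad(phys_min, 8),
                    pad(phys_max, 8), pad(phys_max, 8),
                    pad(dig_min, 8), pad(dig_min, 8),
                    pad(dig_max, 8), pad(dig_max, 8),
                    pad("", 80), pad("", 80),          # prefiltering
                    pad(rate, 8), pad(rate, 8),
                    pad("", 32), pad("", 32))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    writeBin(to_dig(ch1), con, size = 2L, endian = "little")
    writeBin(to_dig(ch2), con, size = 2L, endian = "little")
  }
  close(con)

  rec <- read_recording(p, "edf")
  expect_identical(rec$channel_labels, c("Fz", "Pz"))
  expect_equal(rec$rate, 256)
  expect_equal(ncol(rec$signal), 512L)
  # quantization step is 200/4095 ~ 0.049 uV
  expect_lt(max(abs(rec$signal[1, 1:256] - ch1)), 0.05)
  expect_lt(max(abs(rec$signal[2, 257:512] - ch2)), 0.05)

  # sidecar events are picked up automatically
  ev <- data.frame(trial_id = 1L, kind = c("cue", "onset"),
                   sample = c(10L, 300L), direction = "left")
  utils::write.table(ev, paste0(p, ".events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rec2 <- read_recording(p, "edf")
  expect_equal(nrow(rec2$events), 2L)
  expect_equal(trial_table(rec2)$latency, 290 / 256)
})

test_that("orphan onsets and malformed formats are rejected", {
  sig <- matrix(0, 2, 100)
  ev <- data.frame(trial_id = 1L, kind = "onset", sample = 50L,
                   direction = "up")
  rec <- recording(sig, 64, c("C3", "C4"), ev)
  expect_error(trial_table(rec), "without a matching cue")
  p <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), p)
  expect_error(read_recording(p), "internal recording container")
  expect_error(read_recording(tempfile(), "internal"), "not found")
})

test_that("TSV exports round-trip their tabular content", {
  g <- generate_recording(quick_synth(n_trials = 24, rate = 128))
  cfg <- pipeline_config()
  ep <- scp_epochs(g$recording, cfg)
  wf <- window_features(ep, 0, 0.25, channels = ep$channel_labels[1:3],
                        feature_rate = 16)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  export_window_features(wf, p1)
  back <- utils::read.table(p1, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(back), 24L)
  expect_equal(ncol(back), 2L + 12L)
  expect_equal(as.matrix(back[, -(1:2)]), wf$x, ignore_attr = TRUE)

  grid <- make_grid(c(-0.5, 0), 0.25, 0.0625)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_grid(grid, p2)
  expect_equal(utils::read.table(p2, header = TRUE)$endpoint,
               grid$endpoints)

  cva <- fit_cva(wf$x, wf$labels, wf$provenance)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  export_dp(cva, p3)
  dp <- utils::read.table(p3, header = TRUE, sep = "\t")
  expect_equal(dp$channel, cva$ranking)
  expect_equal(sum(dp$dp), 1, tolerance = 1e-9)

  g2 <- make_grid(c(-0.25, 0), 0.25, 0.0625)
  ts <- run_time_specific(ep, g2, quick_config(n_folds = 3),
                          keep_models = FALSE)
  p4 <- withr::local_tempfile(fileext = ".tsv")
  export_curve(ts, p4)
  cv <- utils::read.table(p4, header = TRUE, sep = "\t")
  expect_equal(cv$da_mean, ts$da_mean)
})
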