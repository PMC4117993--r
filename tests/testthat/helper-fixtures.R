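# Small deterministic fixtures shared across test files.

# a tiny two-channel recording with hand-placed trial events
tiny_recording <- function(n_trials = 4, rate = 64, latency = 2.5,
                           gap = 1.5, seed = 1) {
  set.seed(seed)
  dirs <- rep(direction_labels(), length.out = n_trials)
  cue <- numeric(n_trials)
  onset <- numeric(n_trials)
  t <- 2
  for (i in seq_len(n_trials)) {
    cue[i] <- t
    onset[i] <- t + latency
    t <- onset[i] + gap
  }
  n <- ceiling((t + 2) * rate)
  sig <- matrix(rnorm(2 * n), 2, n)
  ev <- rbind(
    data.frame(trial_id = seq_len(n_trials), kind = "cue",
               sample = round(cue * rate), direction = dirs),
    data.frame(trial_id = seq_len(n_trials), kind = "onset",
               sample = round(onset * rate), direction = dirs))
  recording(sig, rate, c("C3", "C4"), ev)
}

# small synthetic session at the processing rate (fast to generate)
quick_synth <- function(n_trials = 40, snr = 0, seed = 1, rate = 128,
                        channels = default_channel_subset(), ...) {
  synth_config(n_trials = n_trials, channel_labels = channels, rate = rate,
               snr = snr, early_start_fraction = 0, gap_range = c(2, 3),
               rng_seed = seed, ...)
}

# reduced config for fast end-to-end runs
quick_config <- function(...) {
  args <- list(analysis_span = c(-1, 0.25), n_folds = 4L,
               n_permutation_reps = 5L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}

scp_band <- function() band_spec("scp", 0.1, 1, "amplitude")

# epochs of the SCP band signal for a generated recording
scp_epochs <- function(rec, cfg, alignment = "onset",
                       span = cfg$analysis_span) {
  pre <- preprocess_recording(rec, cfg)
  bs <- band_signal_of(pre, scp_band())
  epoch_band(bs, alignment, span)
}
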