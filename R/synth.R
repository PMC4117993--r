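#' Synthetic-recording configuration
#'
#' Describes a self-paced center-out session to simulate: balanced
#' four-direction trials recorded as one continuous multichannel signal with
#' jittered inter-trial gaps, a 1/f-plus-white background per channel, and a
#' direction-coded slow component planted on fronto-parietal channels that
#' builds up before each movement onset. Defaults follow the standard
#' protocol: 240 trials (3 runs of 80), 64-channel extended 10/20 montage at
#' 256 Hz, cue-to-onset latency of at least 2 s (shifted gamma, mean 3 s),
#' and about 4% early starts that violate the 2 s rule and are later
#' discarded.
#'
#' @param n_trials Number of trials.
#' @param channel_labels Montage; defaults to [biosemi64_labels()].
#' @param rate Sampling rate in Hz.
#' @param cue_to_onset List `(min, shape, scale)`: latency is
#'   `min + Gamma(shape, scale)` seconds for compliant trials.
#' @param effect_channels Named list mapping each direction to a named
#'   numeric vector of per-channel gains; `NULL` for the default
#'   fronto-parietal direction code (see [default_effect_channels()]).
#' @param effect_onset Seconds before movement onset at which the planted
#'   component starts (negative).
#' @param effect_band Frequency range (Hz) of the planted component; the
#'   component is low-passed at the band's upper edge.
#' @param snr Planted-component RMS on a unit-gain channel divided by the
#'   background RMS inside `effect_band`. `0` plants nothing.
#' @param noise List `(exponent, pink_sigma, white_sigma)`: 1/f^exponent
#'   background of `pink_sigma` uV RMS plus white noise of `white_sigma` uV
#'   RMS, per channel.
#' @param early_start_fraction Probability that a trial starts before the
#'   2 s minimum (an "early start").
#' @param movement_duration Seconds of sustained effect after onset.
#' @param gap_range Uniform inter-trial gap range in seconds.
#' @param carrier Optional phase-locked oscillatory effect: list
#'   `(freq, snr, phases)` where `phases` gives each direction's
#'   instantaneous phase at movement onset. Amplitude is identical across
#'   directions, so the effect is visible to phase features only.
#' @param rng_seed Integer seed; generation is deterministic given the
#'   configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_trials = 240L,
                         channel_labels = biosemi64_labels(),
                         rate = 256,
                         cue_to_onset = list(min = 2, shape = 2, scale = 0.5),
                         effect_channels = NULL,
                         effect_onset = -0.5,
                         effect_band = c(0.1, 1),
                         snr = 1,
                         noise = list(exponent = 1, pink_sigma = 10,
                                      white_sigma = 2),
                         early_start_fraction = 0.04,
                         movement_duration = 0.6,
                         gap_range = c(2, 4),
                         carrier = NULL,
                         rng_seed = 1L) {
  if (is.null(effect_channels))
    effect_channels <- default_effect_channels()
  if (effect_onset >= 0) stop("effect_onset must be negative")
  if (snr < 0) stop("snr must be >= 0")
  bad <- setdiff(unique(unlist(lapply(effect_channels, names))),
                 channel_labels)
  if (length(bad))
    stop("effect_channels name channels outside the montage: ",
         paste(bad, collapse = ", "))
  if (!setequal(names(effect_channels), direction_labels()))
    stop("effect_channels must be named by the four directions")
  structure(list(
    n_trials = as.integer(n_trials), channel_labels = channel_labels,
    rate = rate, cue_to_onset = cue_to_onset,
    effect_channels = effect_channels, effect_onset = effect_onset,
    effect_band = effect_band, snr = snr, noise = noise,
    early_start_fraction = early_start_fraction,
    movement_duration = movement_duration, gap_range = gap_range,
    carrier = carrier, rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

#' Default direction-coded gain patterns
#'
#' Eight fronto-parietal channels carry the planted component with two
#' orthogonal spatial gradients: up/down flip an anterior-posterior gradient
#' (frontal positive / parietal negative and vice versa), left/right flip a
#' lateral gradient (left-hemisphere positive / right negative). Each
#' direction's gain pattern is normalized to unit Euclidean norm, so the
#' configured SNR measures the total spatial-pattern energy of the planted
#' source against the per-channel background, independent of how many
#' electrodes the pattern spreads over. The four mean patterns are distinct
#' and linearly separable at high SNR, and the channel set is explicit so
#' channel-recovery tests are exact.
#'
#' @return Named list of per-channel gain vectors, one per direction.
#' @export
default_effect_channels <- function() {
  chans <- c("F1", "Fz", "F2", "FCz", "CP1", "CPz", "CP2", "Pz")
  g_ap <- c(1, 1, 1, 1, -1, -1, -1, -1)
  g_lat <- c(1, 0, -1, 0, 1, 0, -1, 0)
  g_ap <- g_ap / sqrt(sum(g_ap^2))
  g_lat <- g_lat / sqrt(sum(g_lat^2))
  names(g_ap) <- names(g_lat) <- chans
  list(up = g_ap, down = -g_ap, left = g_lat, right = -g_lat)
}

local_seed <- function(seed) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    fn <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    fn <- function() rm(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  fn
}

# frequency-domain amplitude weights of the 1/f^a component for an
# even-length real FFT of length m at rate `rate`
pink_weights <- function(m, rate, exponent) {
  f <- c(0, seq_len(m - 1)) * rate / m
  f[f > rate / 2] <- rate - f[f > rate / 2]   # mirrored negative half
  w <- numeric(m)
  w[f > 0] <- f[f > 0]^(-exponent / 2)
  w
}

# expected background RMS inside [lo, hi] Hz, from the synthesis spectrum
background_band_rms <- function(noise, m, rate, lo, hi) {
  w <- pink_weights(m, rate, noise$exponent)
  f <- c(0, seq_len(m - 1)) * rate / m
  f[f > rate / 2] <- rate - f[f > rate / 2]
  in_band <- f >= lo & f <= hi
  pink_var <- noise$pink_sigma^2 * sum(w[in_band]^2) / sum(w^2)
  white_var <- noise$white_sigma^2 * sum(in_band) / m
  sqrt(pink_var + white_var)
}

pink_series <- function(n, m, w, sigma) {
  z <- stats::rnorm(m)
  x <- Re(stats::fft(stats::fft(z) * w, inverse = TRUE)) / m
  x <- x / stats::sd(x) * sigma
  x[seq_len(n)]
}

ramp_plateau <- function(t_rel, effect_onset, plateau_end, release = 0.25) {
  w <- numeric(length(t_rel))
  up <- t_rel >= effect_onset & t_rel < 0
  w[up] <- 0.5 * (1 - cos(pi * (t_rel[up] - effect_onset) / (-effect_onset)))
  w[t_rel >= 0 & t_rel <= plateau_end] <- 1
  dn <- t_rel > plateau_end & t_rel <= plateau_end + release
  w[dn] <- 0.5 * (1 + cos(pi * (t_rel[dn] - plateau_end) / release))
  w
}

# The planted per-trial waveform. A raw monophasic ramp-plateau pulse has
# most of its energy below the low edge of the effect band; a zero-phase
# (non-causal) band-pass turns that out-of-band spectral mass into
# seconds-long acausal tails, leaking direction information far before the
# planted onset. The component is therefore constructed to live inside the
# band from the start: a Hann-windowed slow sine with an integer number of
# cycles (exactly zero area by symmetry), supported on
# [effect_onset, effect_onset + 6|effect_onset|]. Its rising limb is a
# smooth ramp spanning the pre-onset interval, it peaks during the
# movement, and it rings back afterwards like any band-limited transient.
# With the defaults (effect_onset -0.5 s) the support is 3 s and the
# carrier sits at 2/3 Hz, inside the 0.1-1 Hz band, so the analysis
# filter is nearly idempotent on it. The envelope is skewed toward the movement
# (beta-shaped, u^3 (1-u)^2) so that the bulk of the component's energy —
# whose filter tails spread backwards in time under zero-phase filtering —
# sits well after the onset of the build-up, keeping the filtered component
# negligible before effect_onset; a smooth zero-area correction keeps the
# pulse mean-free despite the skew.
planted_waveform <- function(effect_onset, effect_band, rate,
                             n_cycles = 2L) {
  len <- 6 * (-effect_onset)
  f0 <- n_cycles / len
  if (f0 < effect_band[1] || f0 > effect_band[2])
    warning("planted carrier ", signif(f0, 3),
            " Hz lies outside the effect band")
  t_rel <- seq(effect_onset, effect_onset + len, by = 1 / rate)
  u <- (t_rel - effect_onset) / len
  env <- u^3 * (1 - u)^2
  env <- env / max(env)
  w <- sin(2 * pi * n_cycles * u) * env
  hann <- 0.5 * (1 - cos(2 * pi * u))
  w <- w - sum(w) / sum(hann) * hann
  list(t_rel = t_rel, w = w)
}

#' Generate a synthetic self-paced center-out recording
#'
#' Builds the continuous recording described by `cfg`: per-channel 1/f plus
#' white background, cue and onset events per trial, and (for `snr > 0`) a
#' direction-coded slow component — a half-cosine ramp from `effect_onset`
#' to onset followed by a plateau during movement, low-passed at the effect
#' band's upper edge — added on the configured channels. The returned ground
#' truth records every trial's timing, direction and early-start flag plus
#' the planted channel map, enabling exact parameter-recovery tests.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `recording` (an [recording()]) and `truth`
#'   (class `synth_truth`: `$trials` data frame and `$effect` parameters).
#' @export
generate_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  restore <- local_seed(cfg$rng_seed)
  on.exit(restore())
  rate <- cfg$rate
  n_tr <- cfg$n_trials
  dirs <- direction_labels()

  # balanced directions (max class-count difference <= 1), random order
  base <- rep(dirs, floor(n_tr / 4))
  extra <- if (n_tr %% 4) dirs[seq_len(n_tr %% 4)] else character()
  direction <- sample(c(base, extra))

  early <- stats::runif(n_tr) < cfg$early_start_fraction
  lat <- ifelse(
    early,
    stats::runif(n_tr, cfg$cue_to_onset$min - 0.8,
                 cfg$cue_to_onset$min - 0.05),
    cfg$cue_to_onset$min +
      stats::rgamma(n_tr, shape = cfg$cue_to_onset$shape,
                    scale = cfg$cue_to_onset$scale))

  lead_in <- 3; lead_out <- 2
  gaps <- stats::runif(n_tr, cfg$gap_range[1], cfg$gap_range[2])
  cue_t <- numeric(n_tr); onset_t <- numeric(n_tr)
  t <- lead_in
  for (i in seq_len(n_tr)) {
    cue_t[i] <- t
    onset_t[i] <- t + lat[i]
    t <- onset_t[i] + cfg$movement_duration + gaps[i]
  }
  n_samples <- as.integer(ceiling((t + lead_out) * rate))

  n_ch <- length(cfg$channel_labels)
  m <- stats::nextn(n_samples, c(2, 3))
  w <- pink_weights(m, rate, cfg$noise$exponent)
  sig <- matrix(0, n_ch, n_samples)
  for (ch in seq_len(n_ch)) {
    sig[ch, ] <- pink_series(n_samples, m, w, cfg$noise$pink_sigma) +
      stats::rnorm(n_samples, sd = cfg$noise$white_sigma)
  }

  tvec <- (seq_len(n_samples) - 1) / rate
  release <- 0.25
  effect <- list(channels = cfg$effect_channels,
                 effect_onset = cfg$effect_onset,
                 effect_band = cfg$effect_band, snr = cfg$snr,
                 amplitude = 0, movement_duration = cfg$movement_duration)
  if (cfg$snr > 0) {
    bg_rms <- background_band_rms(cfg$noise, m, rate,
                                  cfg$effect_band[1], cfg$effect_band[2])
    wv <- planted_waveform(cfg$effect_onset, cfg$effect_band, rate)
    # unit-gain channel: pre-onset/movement component RMS = snr * bg RMS
    pre_move <- wv$t_rel <= cfg$movement_duration
    amp <- cfg$snr * bg_rms / sqrt(mean(wv$w[pre_move]^2))
    effect$amplitude <- amp
    len <- length(wv$w)
    for (d in dirs) {
      idx_tr <- which(direction == d)
      if (!length(idx_tr)) next
      course <- numeric(n_samples)
      for (i in idx_tr) {
        s0 <- 1L + as.integer(round(
          (onset_t[i] + cfg$effect_onset) * rate))
        sl <- seq.int(s0, s0 + len - 1L)
        ok <- sl >= 1L & sl <= n_samples
        course[sl[ok]] <- course[sl[ok]] + wv$w[ok]
      }
      gains <- cfg$effect_channels[[d]]
      rows <- match(names(gains), cfg$channel_labels)
      sig[rows, ] <- sig[rows, ] + amp * outer(gains, course)
    }
  }

  if (!is.null(cfg$carrier)) {
    car <- cfg$carrier
    bg_rms <- background_band_rms(cfg$noise, m, rate,
                                  max(0.5, car$freq - 3), car$freq + 3)
    amp <- car$snr * bg_rms * sqrt(2)
    chans <- unique(unlist(lapply(cfg$effect_channels, names)))
    rows <- match(chans, cfg$channel_labels)
    for (i in seq_len(n_tr)) {
      s0 <- 1L + as.integer(round((onset_t[i] + cfg$effect_onset) * rate))
      s1 <- 1L + as.integer(round(
        (onset_t[i] + cfg$movement_duration) * rate))
      if (s0 < 1L || s1 > n_samples) next
      tt <- tvec[s0:s1] - onset_t[i]
      env <- ramp_plateau(tt, cfg$effect_onset, cfg$movement_duration,
                          release = 1e-6)
      # smooth the envelope onset so amplitude carries no direction code
      wave <- amp * env * cos(2 * pi * car$freq * tt +
                                car$phases[[direction[i]]])
      sig[rows, s0:s1] <- sig[rows, s0:s1] +
        matrix(wave, length(rows), length(wave), byrow = TRUE)
    }
  }

  cue_sample <- as.integer(round(cue_t * rate))
  onset_sample <- as.integer(round(onset_t * rate))
  events <- rbind(
    data.frame(trial_id = seq_len(n_tr), kind = "cue", sample = cue_sample,
               direction = direction, stringsAsFactors = FALSE),
    data.frame(trial_id = seq_len(n_tr), kind = "onset",
               sample = onset_sample, direction = direction,
               stringsAsFactors = FALSE))
  rec <- recording(sig, rate, cfg$channel_labels, events)

  trials <- data.frame(
    trial_id = seq_len(n_tr), direction = direction,
    cue_s = cue_t, onset_s = onset_t, latency = lat, early = early,
    stringsAsFactors = FALSE)
  truth <- structure(list(trials = trials, effect = effect,
                          config = cfg), class = "synth_truth")
  list(recording = rec, truth = truth)
}

#' Discard early-start trials
#'
#' Removes from the event list every trial whose cue-to-onset latency is
#' below `min_latency` (the protocol's 2 s rule: a movement earlier than 2 s
#' after the cue is a cued reaction, not a self-paced movement). The signal
#' is untouched; removals are reported via a message and recorded in the
#' `"discarded_trials"` attribute.
#'
#' @param rec An [recording()] with paired cue/onset events.
#' @param min_latency Minimum cue-to-onset latency in seconds.
#' @return The recording with offending trials' events removed.
#' @export
discard_early_starts <- function(rec, min_latency = 2) {
  tt <- trial_table(rec)
  bad <- tt$trial_id[tt$latency < min_latency - 1e-9]
  if (length(bad)) {
    message("discarding ", length(bad), " early-start trial(s): ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ...")
    rec$events <- rec$events[!rec$events$trial_id %in% bad, , drop = FALSE]
    rownames(rec$events) <- NULL
  }
  attr(rec, "discarded_trials") <- bad
  rec
}
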