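test_that("chronological folds are contiguous and near-equal", {
  p <- plan_folds(1:10, 5)
  expect_equal(p$assignments$fold, rep(1:5, each = 2))
  sizes <- as.integer(table(plan_folds(1:233, 5)$assignments$fold))
  expect_equal(sizes, c(47L, 47L, 47L, 46L, 46L))
  # blocks preserve order: every fold's ids form a contiguous run
  p3 <- plan_folds(101:140, 4)
  for (f in 1:4) {
    ids <- p3$assignments$trial_id[p3$assignments$fold == f]
    expect_equal(ids, seq(min(ids), max(ids)))
  }
  expect_error(plan_folds(c(3, 1, 2), 2), "recording order")
  expect_error(plan_folds(1:10, 1), ">= 2")
  expect_error(plan_folds(1:3, 5), "more folds")
})

test_that("decoding accuracy is the confusion-matrix trace ratio", {
  perfect <- diag(c(12L, 12L, 12L, 12L))
  dimnames(perfect) <- list(direction_labels(), direction_labels())
  expect_equal(decoding_accuracy(perfect), 1)
  uniform <- matrix(3L, 4, 4)
  expect_equal(decoding_accuracy(uniform), 0.25)
  cm <- matrix(c(10, 2, 1, 0, 1, 8, 2, 1, 2, 1, 6, 2, 1, 2, 2, 5), 4, 4,
               byrow = TRUE)
  expect_equal(decoding_accuracy(cm), 29 / 46)
  expect_error(decoding_accuracy(matrix(0, 4, 4)), "empty")

  cm2 <- confusion_matrix(c("up", "up", "down"), c("up", "down", "down"))
  expect_equal(sum(cm2), 3)
  expect_equal(cm2["up", "down"], 1L)
})

test_that("time-specific decoding separates planted directions near onset", {
  g <- generate_recording(quick_synth(n_trials = 48, snr = 5, seed = 21))
  cfg <- quick_config()
  ep <- scp_epochs(g$recording, cfg)
  grid <- make_grid(cfg$analysis_span, 0.25, 0.0625)
  ts <- run_time_specific(ep, grid, cfg)
  expect_equal(dim(ts$da), c(4L, length(grid$endpoints)))
  expect_true(all(ts$da >= 0 & ts$da <= 1))
  i_near <- which.min(abs(grid$endpoints - (-0.0625)))
  i_far <- which.min(abs(grid$endpoints - (-0.75)))
  expect_gt(ts$da_mean[i_near], ts$da_mean[i_far] + 0.2)
  # every test trial scored exactly once per window
  expect_equal(sum(ts$confusion[[1]]), 48)
  # single-window grid gives a curve of length one
  g1 <- make_grid(c(-0.25, 0), 0.25, 0.0625)
  ts1 <- run_time_specific(ep, g1, cfg)
  expect_length(ts1$da_mean, 1L)
})

test_that("no training information leaks from test labels", {
  g <- generate_recording(quick_synth(n_trials = 24, snr = 1, seed = 31))
  cfg <- quick_config(n_folds = 3)
  ep <- scp_epochs(g$recording, cfg)
  grid <- make_grid(c(-0.25, 0.25), 0.25, 0.125)
  ts1 <- run_time_specific(ep, grid, cfg)
  ep2 <- ep
  # corrupt the labels of fold-1 test trials (first 8 chronological)
  ep2$labels[1:8] <- sample(direction_labels(), 8, replace = TRUE)
  ts2 <- run_time_specific(ep2, grid, cfg)
  m1 <- ts1$models[[1]][[1]]
  m2 <- ts2$models[[1]][[1]]
  expect_identical(serialize(m1, NULL, version = 2L),
                   serialize(m2, NULL, version = 2L))
})

test_that("permutation chance level sits at 1/4 and is reproducible", {
  g <- generate_recording(quick_synth(n_trials = 48, snr = 0, seed = 41))
  cfg <- quick_config()
  ep <- scp_epochs(g$recording, cfg)
  grid <- make_grid(c(-0.5, 0), 0.25, 0.25)
  ch1 <- chance_level(ep, grid, cfg, n_reps = 5, seed = 7)
  ch2 <- chance_level(ep, grid, cfg, n_reps = 5, seed = 7)
  expect_identical(ch1$draws, ch2$draws)
  expect_equal(dim(ch1$draws), c(5L, 4L, 2L))
  expect_lt(abs(mean(ch1$draws) - 0.25), 0.06)
  ch3 <- chance_level(ep, grid, cfg, n_reps = 5, seed = 8)
  expect_false(identical(ch1$draws, ch3$draws))
})

test_that("chance level in refit mode reuses the unpermuted selection", {
  g <- generate_recording(quick_synth(n_trials = 48, snr = 0, seed = 43))
  cfg <- quick_config(n_folds = 3, chance_mode = "refit")
  ep <- scp_epochs(g$recording, cfg)
  grid <- make_grid(c(-0.25, 0), 0.25, 0.25)
  expect_error(chance_level(ep, grid, cfg), "refit mode needs")
  ts <- run_time_specific(ep, grid, cfg)
  ch <- chance_level(ep, grid, cfg, n_reps = 3, ts = ts)
  expect_equal(dim(ch$draws), c(3L, 3L, 1L))
  expect_true(all(ch$draws >= 0 & ch$draws <= 1))
})

test_that("early detection follows the consecutive-significance rule", {
  mk_curve <- function(da_mean_by_window, n_folds = 5) {
    da <- vapply(da_mean_by_window, function(m)
      pmin(1, pmax(0, m + seq(-0.02, 0.02, length.out = n_folds))),
      numeric(n_folds))          # folds x windows
    structure(list(endpoints = seq(-0.5, by = 0.0625,
                                   length.out = length(da_mean_by_window)),
                   da = da, da_mean = colMeans(da),
                   da_sd = apply(da, 2, sd), fold_plan = NULL,
                   mode = "time_specific", period = "onset"),
              class = "decoding_curve")
  }
  mk_chance <- function(n_windows, n_reps = 10, n_folds = 5, seed = 1) {
    set.seed(seed)
    structure(list(
      draws = array(0.25 + rnorm(n_reps * n_folds * n_windows, 0, 0.03),
                    c(n_reps, n_folds, n_windows)),
      endpoints = seq(-0.5, by = 0.0625, length.out = n_windows)),
      class = "chance_level")
  }
  # flat at chance: no detection
  flat <- mk_curve(rep(0.25, 10))
  det <- early_detection(flat, mk_chance(10), k_consecutive = 5)
  expect_true(is.na(det$time))
  # all windows clearly above: detection at the first endpoint
  high <- mk_curve(rep(0.8, 10))
  det2 <- early_detection(high, mk_chance(10), k_consecutive = 5)
  expect_equal(det2$time, -0.5)
  # significance starting at the 4th window
  step <- mk_curve(c(0.25, 0.25, 0.25, rep(0.8, 7)))
  det3 <- early_detection(step, mk_chance(10), k_consecutive = 5)
  expect_equal(det3$time, -0.5 + 3 * 0.0625)
  expect_length(det3$pvalues, 10L)
  # a run shorter than k does not trigger
  blip <- mk_curve(c(0.25, 0.8, 0.8, 0.8, 0.25, 0.25, 0.25, 0.25, 0.25,
                     0.25))
  det4 <- early_detection(blip, mk_chance(10), k_consecutive = 5)
  expect_true(is.na(det4$time))
  expect_error(early_detection(mk_curve(rep(0.5, 3)), mk_chance(3),
                               k_consecutive = 5), "fewer windows")
})

test_that("best-window selection honors the pre-onset and tie rules", {
  g <- generate_recording(quick_synth(n_trials = 24, snr = 0, seed = 51))
  cfg <- quick_config(n_folds = 3)
  ep <- scp_epochs(g$recording, cfg)
  grid <- make_grid(c(-0.5, 0.25), 0.25, 0.0625)
  ts <- run_time_specific(ep, grid, cfg)
  # monotone increasing pre-onset DA: the last pre-onset endpoint wins
  ts$da_mean <- seq(0.2, 0.9, length.out = length(ts$endpoints))
  sel <- select_best_window(ts)
  expect_equal(sel$window_endpoint, 0)
  # flat curve: tie broken toward the endpoint closest to onset
  ts$da_mean[] <- 0.5
  expect_equal(select_best_window(ts)$window_endpoint, 0)
  # post-onset windows never win
  ts$da_mean[ts$endpoints > 0] <- 1
  expect_equal(select_best_window(ts)$window_endpoint, 0)
  ts$models <- NULL
  expect_error(select_best_window(ts), "keep_models")
})

test_that("the selected classifier reproduces its own training window", {
  g <- generate_recording(quick_synth(n_trials = 36, snr = 4, seed = 61))
  cfg <- quick_config(n_folds = 3)
  ep <- scp_epochs(g$recording, cfg)
  grid <- make_grid(cfg$analysis_span, 0.25, 0.0625)
  ts <- run_time_specific(ep, grid, cfg)
  sel <- select_best_window(ts)
  rs <- run_selected(sel, ep, grid, cfg)
  i <- which(abs(grid$endpoints - sel$window_endpoint) < 1e-9)
  expect_equal(rs$da[, i], ts$da[, i])
  expect_equal(rs$mode, "selected")
  # channel mismatch is an error
  ep_bad <- ep
  ep_bad$channel_labels <- rev(ep$channel_labels)
  expect_error(run_selected(sel, ep_bad, grid, cfg), "channel mismatch")
})

test_that("band comparison ranks the planted band first", {
  g <- generate_recording(quick_synth(n_trials = 32, snr = 5, seed = 71))
  cfg <- quick_config(n_folds = 4, analysis_span = c(-0.5, 0.25))
  bands <- list(scp_band(), band_spec("low_gamma", 30, 45, "envelope"))
  out <- band_comparison(g$recording, bands, cfg)
  expect_named(out, c("scp", "low_gamma"))
  expect_gt(max(out$scp$curve$da_mean), max(out$low_gamma$curve$da_mean))
  expect_equal(band_comparison(g$recording, list(), cfg), list())
})

test_that("decoding accuracy does not decrease with planted snr", {
  best_da <- vapply(c(0, 2, 5), function(s) {
    g <- generate_recording(quick_synth(n_trials = 32, snr = s, seed = 81))
    cfg <- quick_config(n_folds = 4, analysis_span = c(-0.25, 0))
    ep <- scp_epochs(g$recording, cfg)
    grid <- make_grid(cfg$analysis_span, 0.25, 0.0625)
    max(run_time_specific(ep, grid, cfg, keep_models = FALSE)$da_mean)
  }, 0)
  expect_true(all(diff(best_da) >= -1e-9))
})
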