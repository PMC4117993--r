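#' Chronological cross-validation folds
#'
#' Splits trials into `n_folds` contiguous blocks in chronological order
#' (block sizes differ by at most one, earlier blocks taking the remainder).
#' Block `k` is the test fold of round `k`; the remaining trials train.
#' Chronological blocking avoids the optimistic bias of random splitting on
#' slowly drifting recordings.
#'
#' @param trial_ids Trial identifiers in recording (chronological) order;
#'   out-of-order input is rejected.
#' @param n_folds Number of folds (>= 2, <= number of trials).
#' @return A `fold_plan`: data frame (`trial_id`, `fold`) plus `n_folds`.
#' @export
plan_folds <- function(trial_ids, n_folds) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  n <- length(trial_ids)
  if (n_folds > n) stop("more folds than trials")
  if (is.unsorted(trial_ids, strictly = TRUE))
    stop("trial_ids must be supplied in recording order")
  sizes <- rep(n %/% n_folds, n_folds) +
    (seq_len(n_folds) <= n %% n_folds)
  structure(list(
    assignments = data.frame(trial_id = trial_ids,
                             fold = rep(seq_len(n_folds), times = sizes)),
    n_folds = as.integer(n_folds)
  ), class = "fold_plan")
}

#' Confusion matrix of direction predictions
#'
#' @param actual,predicted Label vectors of equal length.
#' @param labels Class labels fixing row/column order (default
#'   [direction_labels()]).
#' @return Integer matrix, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted,
                             labels = direction_labels()) {
  cm <- table(factor(actual, levels = labels),
              factor(predicted, levels = labels))
  m <- matrix(as.integer(cm), length(labels), length(labels),
              dimnames = list(actual = labels, predicted = labels))
  m
}

#' Decoding accuracy
#'
#' The ratio of correctly classified trials (the confusion-matrix trace) to
#' all test trials. 1 denotes perfect separation; chance is 1/4 for the
#' balanced four-direction task.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar in \[0, 1\].
#' @export
decoding_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

standardize_stats <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  list(center = mu, scale = sdev)
}

apply_standardize <- function(x, st) {
  sweep(sweep(x, 2L, st$center, "-"), 2L, st$scale, "/")
}

# collapse a stacked window-feature matrix to per-channel window means
channel_mean_features <- function(x, prov) {
  chans <- unique(prov$channel)
  xm <- vapply(chans, function(ch)
    rowMeans(x[, prov$channel == ch, drop = FALSE]), numeric(nrow(x)))
  list(x = matrix(xm, nrow = nrow(x)),
       provenance = data.frame(channel = chans, stringsAsFactors = FALSE))
}

# one window, one fold: standardize on train, CVA-select channels, fit LDA
# on the selected channels' columns, score the test trials
fit_window_fold <- function(wf, train_idx, test_idx, cfg,
                            train_labels = NULL) {
  if (is.null(train_labels)) train_labels <- wf$labels[train_idx]
  st <- standardize_stats(wf$x[train_idx, , drop = FALSE])
  xtr <- apply_standardize(wf$x[train_idx, , drop = FALSE], st)
  if (cfg$cva_mode == "channel_mean") {
    cm <- channel_mean_features(xtr, wf$provenance)
    cva <- fit_cva(cm$x, train_labels, cm$provenance,
                   standardize = FALSE, ridge = cfg$cva_ridge)
  } else {
    cva <- fit_cva(xtr, train_labels, wf$provenance,
                   standardize = FALSE, ridge = cfg$cva_ridge)
  }
  sel <- select_top_channels(cva, cfg$n_select_channels)
  mask <- wf$provenance$channel %in% sel
  lda <- fit_lda(xtr[, mask, drop = FALSE], train_labels,
                 shrinkage = cfg$shrinkage)
  xte <- apply_standardize(wf$x[test_idx, , drop = FALSE], st)
  pred <- predict(lda, xte[, mask, drop = FALSE])
  cm_te <- confusion_matrix(wf$labels[test_idx], pred)
  list(da = decoding_accuracy(cm_te), cm = cm_te,
       model = list(standardize = st, channels = sel, mask = mask,
                    lda = lda, ranking = cva$ranking,
                    dp_per_channel = cva$dp_per_channel))
}

extract_all_windows <- function(epochs, grid, cfg) {
  lapply(grid$endpoints, function(e)
    window_features(epochs, e, window_len = cfg$window_len,
                    feature_rate = cfg$feature_rate,
                    phase_encoding = cfg$phase_encoding))
}

fold_indices <- function(plan, trial_ids) {
  lapply(seq_len(plan$n_folds), function(f) {
    ids <- plan$assignments$trial_id[plan$assignments$fold == f]
    which(trial_ids %in% ids)
  })
}

#' Time-specific decoding curve
#'
#' For every window endpoint of the grid, runs the full per-fold chain —
#' feature standardization, CVA channel selection and LDA fit on the
#' training block, scoring on the chronological test block — and records the
#' decoding accuracy per fold. Every test trial is scored exactly once per
#' window.
#'
#' @param epochs An [epoch_band()] result (onset-aligned for the intention
#'   period).
#' @param grid A [make_grid()] over the epoch span.
#' @param cfg A [pipeline_config()].
#' @param keep_models Keep the per-window, per-fold fitted models (needed by
#'   [select_best_window()]).
#' @return A `decoding_curve`: `endpoints`, `da` (folds x windows), `da_mean`,
#'   `da_sd`, `confusion` (summed over folds, per window), `models`,
#'   `fold_plan`, `mode = "time_specific"`, `period`.
#' @export
run_time_specific <- function(epochs, grid, cfg = pipeline_config(),
                              keep_models = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "window_grid"))
  feats <- extract_all_windows(epochs, grid, cfg)
  plan <- plan_folds(epochs$trial_ids, cfg$n_folds)
  folds <- fold_indices(plan, epochs$trial_ids)
  n_e <- length(grid$endpoints)
  da <- matrix(NA_real_, cfg$n_folds, n_e)
  confusion <- vector("list", n_e)
  models <- if (keep_models) vector("list", n_e) else NULL
  for (e in seq_len(n_e)) {
    cms <- NULL
    if (keep_models) models[[e]] <- vector("list", cfg$n_folds)
    for (f in seq_len(cfg$n_folds)) {
      te <- folds[[f]]
      tr <- setdiff(seq_along(epochs$trial_ids), te)
      r <- fit_window_fold(feats[[e]], tr, te, cfg)
      da[f, e] <- r$da
      cms <- if (is.null(cms)) r$cm else cms + r$cm
      if (keep_models) models[[e]][[f]] <- r$model
    }
    confusion[[e]] <- cms
  }
  structure(list(
    endpoints = grid$endpoints, da = da,
    da_mean = colMeans(da), da_sd = apply(da, 2L, stats::sd),
    confusion = confusion, models = models, fold_plan = plan,
    grid = grid, mode = "time_specific", period = epochs$alignment,
    channel_labels = epochs$channel_labels
  ), class = "decoding_curve")
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat(sprintf(
    "<decoding_curve> %s/%s: %d windows [%g, %g] s, peak mean DA %.3f at %g s\n",
    x$mode, x$period, length(x$endpoints), min(x$endpoints),
    max(x$endpoints), max(x$da_mean), x$endpoints[which.max(x$da_mean)]))
  invisible(x)
}

#' Permutation chance level
#'
#' Estimates the empirical chance level of the decoding chain by rerunning
#' the cross-validation with the training labels randomly permuted:
#' `n_reps` repetitions x `n_folds` folds, one fresh permutation per
#' repetition and fold (shared across windows), scored against the intact
#' test labels. In `"full"` mode (default) each permutation reruns CVA
#' selection as well, so selection bias under the null is included;
#' `"refit"` mode reuses the channel selection of `ts` and refits only the
#' classifier.
#'
#' @param epochs,grid,cfg As in [run_time_specific()].
#' @param n_reps Number of permutation repetitions (default from `cfg`).
#' @param seed Seed of the permutation stream (default `cfg$rng_seed`).
#' @param ts A [run_time_specific()] result with models; required for
#'   `"refit"` mode.
#' @return A `chance_level` object: `draws` (reps x folds x windows array of
#'   DA), `chance_mean` per window, `endpoints`.
#' @export
chance_level <- function(epochs, grid, cfg = pipeline_config(),
                         n_reps = cfg$n_permutation_reps,
                         seed = cfg$rng_seed, ts = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "window_grid"))
  if (cfg$chance_mode == "refit" && (is.null(ts) || is.null(ts$models)))
    stop("refit mode needs a time-specific result with kept models")
  restore <- local_seed(seed)
  on.exit(restore())
  feats <- extract_all_windows(epochs, grid, cfg)
  plan <- plan_folds(epochs$trial_ids, cfg$n_folds)
  folds <- fold_indices(plan, epochs$trial_ids)
  n_e <- length(grid$endpoints)
  draws <- array(NA_real_, c(n_reps, cfg$n_folds, n_e))
  for (rep_i in seq_len(n_reps)) {
    for (f in seq_len(cfg$n_folds)) {
      te <- folds[[f]]
      tr <- setdiff(seq_along(epochs$trial_ids), te)
      perm <- sample(epochs$labels[tr])
      for (e in seq_len(n_e)) {
        if (cfg$chance_mode == "full") {
          r <- fit_window_fold(feats[[e]], tr, te, cfg,
                               train_labels = perm)
          draws[rep_i, f, e] <- r$da
        } else {
          m <- ts$models[[e]][[f]]
          xtr <- apply_standardize(feats[[e]]$x[tr, , drop = FALSE],
                                   m$standardize)
          lda <- fit_lda(xtr[, m$mask, drop = FALSE], perm,
                         shrinkage = cfg$shrinkage)
          xte <- apply_standardize(feats[[e]]$x[te, , drop = FALSE],
                                   m$standardize)
          pred <- predict(lda, xte[, m$mask, drop = FALSE])
          draws[rep_i, f, e] <- decoding_accuracy(
            confusion_matrix(feats[[e]]$labels[te], pred))
        }
      }
    }
  }
  structure(list(draws = draws,
                 chance_mean = apply(draws, 3L, mean),
                 endpoints = grid$endpoints, n_reps = n_reps),
            class = "chance_level")
}

#' Early detection of above-chance decoding
#'
#' Per window, the fold decoding accuracies are compared with the
#' permutation chance draws of the same window by a one-sided Wilcoxon
#' rank-sum test (decoding greater than chance). The detection time is the
#' endpoint of the first window that begins a run of `k_consecutive`
#' windows all significant at `alpha`. With `pre_onset_only = TRUE`
#' (default) only runs beginning at or before the alignment event (endpoint
#' <= 0) count as early detection.
#'
#' @param curve A [run_time_specific()] decoding curve.
#' @param chance The matching [chance_level()].
#' @param alpha Significance level.
#' @param k_consecutive Required run length.
#' @param pre_onset_only Restrict detection to endpoints <= 0.
#' @return List with `time` (s, or `NA` when no qualifying run exists),
#'   `pvalues` and `significant` per window.
#' @export
early_detection <- function(curve, chance, alpha = 0.05,
                            k_consecutive = 5L, pre_onset_only = TRUE) {
  stopifnot(inherits(curve, "decoding_curve"),
            inherits(chance, "chance_level"))
  if (!isTRUE(all.equal(curve$endpoints, chance$endpoints)))
    stop("curve and chance were computed on different grids")
  n_e <- length(curve$endpoints)
  if (n_e < k_consecutive)
    stop("fewer windows than the required consecutive run")
  pv <- vapply(seq_len(n_e), function(e) {
    suppressWarnings(stats::wilcox.test(
      curve$da[, e], as.numeric(chance$draws[, , e]),
      alternative = "greater", exact = FALSE)$p.value)
  }, 0)
  sig <- pv < alpha
  time <- NA_real_
  for (i in seq_len(n_e - k_consecutive + 1L)) {
    if (all(sig[i:(i + k_consecutive - 1L)])) {
      if (!pre_onset_only || curve$endpoints[i] <= 1e-9) {
        time <- curve$endpoints[i]
        break
      }
    }
  }
  list(time = time, pvalues = pv, significant = sig)
}

#' Select the best pre-onset window
#'
#' Picks the window endpoint at or before movement onset with the highest
#' mean decoding accuracy (ties go to the later endpoint, closer to onset)
#' and freezes each fold's standardization, channel selection and LDA model
#' for reuse across other windows and the idle period. Windows after onset
#' reflect execution rather than intention and are excluded.
#'
#' @param curve A [run_time_specific()] result with kept models.
#' @return A `selected_classifier`: `window_endpoint`, `fold_models`,
#'   `fold_plan`, `da_mean` at the selected window.
#' @export
select_best_window <- function(curve) {
  stopifnot(inherits(curve, "decoding_curve"))
  if (is.null(curve$models))
    stop("curve was run with keep_models = FALSE")
  pre <- which(curve$endpoints <= 1e-9)
  if (!length(pre)) stop("no pre-onset window endpoint in the curve")
  m <- curve$da_mean[pre]
  best <- pre[max(which(m == max(m)))]
  structure(list(
    window_endpoint = curve$endpoints[best],
    fold_models = curve$models[[best]],
    fold_plan = curve$fold_plan,
    da_mean = curve$da_mean[best],
    channel_labels = curve$channel_labels,
    mode = "selected"
  ), class = "selected_classifier")
}

#' Score the selected classifier across windows
#'
#' Applies the frozen per-fold models of the selected window to every
#' endpoint of `grid`, each fold scoring only its own chronological test
#' trials: the sensitivity analysis on onset-aligned epochs, the
#' specificity analysis on cue-aligned idle epochs. No model parameter is
#' refit.
#'
#' @param selected A [select_best_window()] result.
#' @param epochs Onset- or cue-aligned [epoch_band()] epochs with the same
#'   channel set the classifier was trained on.
#' @param grid A [make_grid()] over the epoch span.
#' @param cfg A [pipeline_config()].
#' @return A `decoding_curve` with `mode = "selected"`.
#' @export
run_selected <- function(selected, epochs, grid, cfg = pipeline_config()) {
  stopifnot(inherits(selected, "selected_classifier"),
            inherits(epochs, "epoch_set"), inherits(grid, "window_grid"))
  if (!identical(selected$channel_labels, epochs$channel_labels))
    stop("channel mismatch between the frozen selection and the epochs")
  feats <- extract_all_windows(epochs, grid, cfg)
  folds <- fold_indices(selected$fold_plan, epochs$trial_ids)
  n_e <- length(grid$endpoints)
  n_f <- selected$fold_plan$n_folds
  da <- matrix(NA_real_, n_f, n_e)
  confusion <- vector("list", n_e)
  for (e in seq_len(n_e)) {
    cms <- NULL
    for (f in seq_len(n_f)) {
      te <- folds[[f]]
      if (!length(te)) next
      m <- selected$fold_models[[f]]
      xte <- apply_standardize(feats[[e]]$x[te, , drop = FALSE],
                               m$standardize)
      pred <- predict(m$lda, xte[, m$mask, drop = FALSE])
      cm <- confusion_matrix(feats[[e]]$labels[te], pred)
      da[f, e] <- decoding_accuracy(cm)
      cms <- if (is.null(cms)) cm else cms + cm
    }
    confusion[[e]] <- cms
  }
  structure(list(
    endpoints = grid$endpoints, da = da,
    da_mean = colMeans(da, na.rm = TRUE),
    da_sd = apply(da, 2L, stats::sd, na.rm = TRUE),
    confusion = confusion, models = NULL, fold_plan = selected$fold_plan,
    grid = grid, mode = "selected", period = epochs$alignment,
    channel_labels = epochs$channel_labels
  ), class = "decoding_curve")
}

#' Per-band decoding comparison
#'
#' Runs the complete pipeline — preprocessing, band filtering, onset-aligned
#' epoching, time-specific cross-validated decoding — once per frequency
#' band, to compare where direction information lives across the spectrum.
#'
#' @param rec Raw [recording()].
#' @param bands List of [band_spec()]s (may be empty).
#' @param cfg A [pipeline_config()].
#' @param with_chance Also compute each band's permutation chance level.
#' @return Named list (one element per band) of lists with `curve` and
#'   optionally `chance`.
#' @export
band_comparison <- function(rec, bands, cfg = pipeline_config(),
                            with_chance = FALSE) {
  if (!length(bands)) return(list())
  pre <- preprocess_recording(rec, cfg)
  grid <- make_grid(cfg$analysis_span, cfg$window_len, cfg$window_step)
  out <- lapply(bands, function(b) {
    bs <- band_signal_of(pre, b)
    ep <- epoch_band(bs, "onset", cfg$analysis_span)
    res <- list(curve = run_time_specific(ep, grid, cfg,
                                          keep_models = FALSE))
    if (with_chance) res$chance <- chance_level(ep, grid, cfg)
    res
  })
  names(out) <- vapply(bands, function(b) b$name, "")
  out
}
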