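#' Canonical variate analysis for channel selection
#'
#' Solves the multi-class discriminant eigenproblem `B v = lambda W v`
#' (between-class vs within-class scatter) and derives a discriminant power
#' (DP) score per feature and per channel. The canonical weight vectors are
#' W-normalized (`v' W v = 1`); the DP of feature `j` is the
#' eigenvalue-weighted sum of its squared coefficients,
#' `sum_k lambda_k v_jk^2`, normalized to sum to 1 over features. Channel DP
#' sums the DP of that channel's columns. With `g` classes at most `g - 1`
#' eigenvalues are nonzero.
#'
#' The within-class scatter is regularized with a scaled-identity ridge
#' `W + eps * trace(W)/p * I`, with `eps` escalated tenfold until the
#' Cholesky factorization is well-conditioned; the ridge actually used is
#' returned. When the scatter is structurally rank deficient (fewer
#' within-class degrees of freedom than features) the ridge is escalated
#' directly to one average eigenvalue (`eps = 1`), the usual
#' regularized-discriminant-analysis shrinkage, since otherwise the
#' data-free null-space directions dominate the eigenvalue spectrum and
#' the discriminant-power ranking degenerates to noise.
#'
#' @param x Trials x features numeric matrix.
#' @param labels Class label per trial (>= 2 trials per class).
#' @param provenance Optional data frame with a `channel` column per feature
#'   (as produced by [window_features()]); enables per-channel DP.
#' @param standardize Standardize each feature to zero mean / unit variance
#'   before solving (the same statistics must then be applied to any data
#'   scored with the selected features).
#' @param ridge Initial ridge factor `eps`.
#' @param n_select If given, also store the top-`n_select` channel names.
#' @return A `cva_result`: `eigenvalues`, `weights` (features x canonical
#'   variates), `dp_per_feature`, `dp_per_channel`, `channels`, `ranking`,
#'   `selected`, `ridge_used`.
#' @export
fit_cva <- function(x, labels, provenance = NULL, standardize = TRUE,
                    ridge = 1e-6, n_select = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 trials")
  if (standardize) {
    mu <- colMeans(x)
    sdev <- apply(x, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdev, "/")
  }
  p <- ncol(x)
  g <- length(counts)
  grand <- colMeans(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (cl in names(counts)) {
    xc <- x[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    xc <- sweep(xc, 2L, mc, "-")
    W <- W + crossprod(xc)
    d <- mc - grand
    B <- B + nrow(xc) * tcrossprod(d)
  }

  eps <- ridge
  # with fewer than p within-class degrees of freedom the scatter cannot be
  # full rank; no infinitesimal ridge can make its null space meaningful,
  # so shrink by a full unit of the average eigenvalue (the standard
  # regularized-discriminant-analysis remedy), which keeps noise directions
  # from dominating the eigenvalue spectrum
  if (nrow(x) - g < p) eps <- max(eps, 1)
  scale_I <- sum(diag(W)) / p
  if (scale_I == 0) scale_I <- 1
  repeat {
    Wr <- W + eps * scale_I * diag(p)
    R <- tryCatch(chol(Wr), error = function(e) NULL)
    ok <- !is.null(R) && (min(diag(R)) / max(diag(R)))^2 > 1e-12
    if (ok || eps > 1e-2) break
    eps <- eps * 10
  }
  if (is.null(R)) stop("within-class scatter could not be regularized")

  # whiten: M = R^-T B R^-1 is symmetric; eigenvectors map back by R^-1
  M <- backsolve(R, t(backsolve(R, B, transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  k <- min(g - 1L, p)
  lambda <- pmax(es$values[seq_len(k)], 0)
  V <- backsolve(R, es$vectors[, seq_len(k), drop = FALSE])

  dp_feat <- as.numeric((V^2) %*% lambda)
  tot <- sum(dp_feat)
  if (tot > 0) dp_feat <- dp_feat / tot
  res <- list(eigenvalues = lambda, weights = V, dp_per_feature = dp_feat,
              ridge_used = eps)
  if (!is.null(provenance)) {
    chans <- unique(provenance$channel)
    dp_ch <- vapply(chans, function(ch)
      sum(dp_feat[provenance$channel == ch]), 0)
    res$dp_per_channel <- dp_ch
    res$channels <- chans
    res$ranking <- rank_channels(dp_ch, chans)
    if (!is.null(n_select))
      res$selected <- res$ranking[seq_len(n_select)]
  }
  structure(res, class = "cva_result")
}

# descending dp; exact ties keep the original (montage) channel order
rank_channels <- function(dp, channels) {
  channels[order(-dp, seq_along(dp))]
}

#' Top channels by discriminant power
#'
#' First `n` channels of the CVA ranking. Ties in DP are broken by the
#' original channel-list order, so selection is deterministic.
#'
#' @param result A [fit_cva()] result fitted with `provenance`.
#' @param n Number of channels to keep (`n <=` number of channels).
#' @return Character vector of `n` channel names.
#' @export
select_top_channels <- function(result, n) {
  stopifnot(inherits(result, "cva_result"))
  if (is.null(result$ranking))
    stop("CVA was fitted without channel provenance")
  if (n > length(result$ranking))
    stop("n exceeds the number of channels")
  result$ranking[seq_len(n)]
}
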