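#' Linear discriminant analysis with pooled covariance
#'
#' Four-class (or general multi-class) LDA: each class is modeled as a
#' Gaussian with its own mean and one covariance matrix shared by all
#' classes, and a sample is assigned to the class with the largest posterior
#' probability under Bayes' rule. The pooled covariance is the within-class
#' covariance pooled over classes, optionally shrunk toward scaled identity:
#' `(1 - s) * S + s * (trace(S)/p) * I`. Priors are the empirical class
#' frequencies. Numerics go through a Cholesky factorization of the
#' covariance (no explicit inverse) and posteriors are normalized in log
#' space.
#'
#' @param x Trials x features numeric matrix (finite).
#' @param labels Class label per trial; every class needs >= 2 trials.
#' @param shrinkage Shrinkage weight `s` in \[0, 1\] (default 0.05).
#' @return An `lda_model`: `class_labels`, `means` (classes x features),
#'   `pooled_cov`, `priors`, `shrinkage`, `dim`.
#' @export
fit_lda <- function(x, labels, shrinkage = 0.05) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 trials")
  cls <- names(counts)
  p <- ncol(x)
  n <- nrow(x)
  g <- length(cls)
  means <- matrix(0, g, p, dimnames = list(cls, colnames(x)))
  S <- matrix(0, p, p)
  for (cl in cls) {
    xc <- x[labels == cl, , drop = FALSE]
    means[cl, ] <- colMeans(xc)
    S <- S + crossprod(sweep(xc, 2L, means[cl, ], "-"))
  }
  S <- S / (n - g)
  S <- (S + t(S)) / 2
  tr <- sum(diag(S))
  if (tr == 0) {
    warning("degenerate (zero) pooled covariance; using identity, ",
            "posteriors reduce to the class priors where means coincide")
    sigma <- diag(p)
  } else {
    sigma <- (1 - shrinkage) * S + shrinkage * (tr / p) * diag(p)
  }
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) {
    if (shrinkage == 0)
      stop("pooled covariance is singular; use shrinkage > 0")
    warning("pooled covariance numerically singular; escalating shrinkage")
    sigma <- 0.5 * S + 0.5 * (tr / p) * diag(p)
    R <- chol(sigma)
  }
  structure(list(class_labels = cls, means = means, pooled_cov = sigma,
                 chol = R, priors = as.numeric(counts) / n,
                 shrinkage = shrinkage, dim = p),
            class = "lda_model")
}

#' Class posterior probabilities
#'
#' Posterior `P(C = y | x)` for each class: prior times the shared-covariance
#' Gaussian density, normalized over classes. Computed via log-space
#' discriminants and log-sum-exp, so each row sums to 1 to machine
#' precision.
#'
#' @param model An [fit_lda()] model.
#' @param x Feature vector or trials x features matrix.
#' @return Matrix (trials x classes) of posterior probabilities.
#' @export
posterior <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$dim)
    stop("feature dimension ", ncol(x), " does not match model dim ",
         model$dim)
  if (!all(is.finite(x))) stop("features must be finite")
  g <- length(model$class_labels)
  logd <- matrix(0, nrow(x), g, dimnames = list(NULL, model$class_labels))
  for (k in seq_len(g)) {
    d <- sweep(x, 2L, model$means[k, ], "-")
    z <- backsolve(model$chol, t(d), transpose = TRUE)
    logd[, k] <- -0.5 * colSums(z^2) + log(model$priors[k])
  }
  mx <- apply(logd, 1L, max)
  pr <- exp(logd - mx)
  pr / rowSums(pr)
}

#' Predict direction labels
#'
#' `argmax_y P(C = y | x)` per trial; posterior ties are broken by the fixed
#' class order of the model.
#'
#' @param object An [fit_lda()] model.
#' @param newdata Feature vector or trials x features matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  post <- posterior(object, newdata)
  object$class_labels[max.col(post, ties.method = "first")]
}
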