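#' Construct a feature table
#'
#' @param X samples x features numeric matrix (may contain `NA` for
#'   unobserved cells).
#' @param mz Numeric feature m/z labels, strictly increasing.
#' @param classes Optional factor/character of per-sample class labels.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(X, mz, classes = NULL) {
  stopifnot(is.matrix(X), length(mz) == ncol(X))
  if (is.unsorted(mz, strictly = TRUE))
    stop("feature m/z labels must be strictly increasing", call. = FALSE)
  if (!is.null(classes)) {
    classes <- factor(classes)
    stopifnot(length(classes) == nrow(X))
  }
  structure(list(X = X, mz = mz, classes = classes),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$X), "samples x", ncol(x$X), "features")
  if (!is.null(x$classes))
    cat(" (", nlevels(x$classes), "classes )")
  cat("\n  missing cells:", sum(is.na(x$X)), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Align peaks across spectra into a feature table
#'
#' Greedy single-linkage clustering of the pooled peak list along m/z: peaks
#' join the current cluster while they fall within `tol_ppm` of its
#' intensity-weighted mean m/z, otherwise they found a new feature. Cells
#' unobserved in a sample are `NA`.
#'
#' @param spectra List of [spectrum()] objects (>= 2).
#' @param classes Optional per-spectrum class labels.
#' @param tol_ppm Merge radius, ppm.
#' @return A [feature_table()].
#' @export
align_features <- function(spectra, classes = NULL, tol_ppm = 20) {
  if (length(spectra) < 2L)
    stop("feature alignment needs at least 2 spectra", call. = FALSE)
  pool <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (nrow(s) == 0L) return(NULL)
    data.frame(sample = i, mz = s$mz, intensity = s$intensity)
  }))
  pool <- pool[order(pool$mz), ]
  cl <- integer(nrow(pool))
  centers <- numeric(0)
  wsum <- numeric(0)
  cur <- 0L
  for (r in seq_len(nrow(pool))) {
    m <- pool$mz[r]; w <- max(pool$intensity[r], .Machine$double.eps)
    if (cur == 0L || abs(m - centers[cur]) / centers[cur] * 1e6 > tol_ppm) {
      cur <- cur + 1L
      centers[cur] <- m
      wsum[cur] <- w
    } else {
      centers[cur] <- (centers[cur] * wsum[cur] + m * w) / (wsum[cur] + w)
      wsum[cur] <- wsum[cur] + w
    }
    cl[r] <- cur
  }
  X <- matrix(NA_real_, length(spectra), cur)
  for (r in seq_len(nrow(pool))) {
    i <- pool$sample[r]
    if (is.na(X[i, cl[r]])) X[i, cl[r]] <- 0
    X[i, cl[r]] <- X[i, cl[r]] + pool$intensity[r]
  }
  o <- order(centers)
  feature_table(X[, o, drop = FALSE], centers[o], classes)
}

#' Drop features with too many missing values
#'
#' Removes features whose missing fraction strictly exceeds `max_missing`
#' (a feature missing in exactly 80% of samples is retained under the
#' default).
#'
#' @param table A [feature_table()].
#' @param max_missing Maximal tolerated missing fraction.
#' @return The filtered `feature_table`.
#' @export
filter_missing <- function(table, max_missing = 0.80) {
  frac <- colMeans(is.na(table$X))
  keep <- frac <= max_missing
  if (!any(keep))
    stop("all features exceed the missing-value threshold", call. = FALSE)
  feature_table(table$X[, keep, drop = FALSE], table$mz[keep],
                table$classes)
}

# observed-data Gaussian log-likelihood under the PPCA model (complete-data
# approximation on the current imputation)
.ppca_loglik <- function(Xc, W, sigma2) {
  n <- nrow(Xc); d <- ncol(Xc); q <- ncol(W)
  Mq <- crossprod(W) + sigma2 * diag(q)
  logdetC <- (d - q) * log(sigma2) + determinant(Mq)$modulus[1]
  Ci_X <- (Xc - Xc %*% W %*% solve(Mq, t(W))) / sigma2   # Woodbury
  -0.5 * (n * d * log(2 * pi) + n * logdetC + sum(Xc * Ci_X))
}

#' Impute missing values by probabilistic PCA
#'
#' Fits the PPCA model `x = W z + mu + eps`, `eps ~ N(0, sigma2 I)`, by EM,
#' treating missing cells as latent: each iteration re-estimates the loading
#' matrix and noise variance from the current completed matrix and replaces
#' the missing cells with the model reconstruction. Observed cells are never
#' altered. Converges when the relative log-likelihood change drops below
#' `tol` (or after `max_iter` iterations, in which case the result carries a
#' `converged = FALSE` attribute and a warning).
#'
#' @param table A [feature_table()] (post missing-value filtering).
#' @param n_components Latent dimension; default `min(5, n_samples - 1)`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return The completed `feature_table` (attribute `converged`).
#' @export
impute_ppca <- function(table, n_components = NULL, tol = 1e-6,
                        max_iter = 1000L) {
  X <- table$X
  n <- nrow(X); d <- ncol(X)
  if (is.null(n_components)) n_components <- min(5L, n - 1L)
  q <- n_components
  if (q >= min(n, d))
    stop("n_components must be smaller than min(samples, features)",
         call. = FALSE)
  mis <- is.na(X)
  if (!any(mis)) {
    attr(table, "converged") <- TRUE
    return(table)
  }
  # deterministic init: column-mean fill, SVD loadings
  mu <- colMeans(X, na.rm = TRUE)
  Xf <- X
  Xf[mis] <- matrix(mu, n, d, byrow = TRUE)[mis]
  ll_old <- -Inf
  converged <- FALSE
  obs_scale <- stats::sd(X[!mis])
  for (it in seq_len(max_iter)) {
    mu <- colMeans(Xf)
    Xc <- sweep(Xf, 2, mu)
    sv <- svd(Xc, nu = q, nv = q)
    lam <- sv$d^2 / n
    # noise floor keeps the model proper when the data are exactly low rank
    sigma2 <- max(mean(lam[-seq_len(q)]), 1e-10 * lam[1], 1e-12)
    W <- sv$v %*% diag(sqrt(pmax(lam[seq_len(q)] - sigma2, 0)), q)
    # posterior mean reconstruction
    Mq <- crossprod(W) + sigma2 * diag(q)
    Z <- Xc %*% W %*% solve(Mq)
    recon <- sweep(Z %*% t(W), 2, -mu)
    delta <- sqrt(mean((Xf[mis] - recon[mis])^2)) / (obs_scale + tol)
    Xf[mis] <- recon[mis]
    ll <- .ppca_loglik(sweep(Xf, 2, colMeans(Xf)), W, sigma2)
    if (delta < tol ||
        (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("PPCA imputation did not converge within ", max_iter,
            " iterations", call. = FALSE)
  out <- feature_table(Xf, table$mz, table$classes)
  attr(out, "converged") <- converged
  out
}

#' Filter features by interquartile range
#'
#' Ranks features by their IQR across samples and drops the least variable
#' `drop_fraction` of them (constant features go first).
#'
#' @param table A [feature_table()] without missing values.
#' @param drop_fraction Fraction of features to drop, in `[0, 1)`.
#' @return The filtered `feature_table`.
#' @export
iqr_filter <- function(table, drop_fraction = 0.25) {
  if (drop_fraction >= 1) stop("drop_fraction must be < 1", call. = FALSE)
  if (nrow(table$X) < 4L)
    stop("IQR filtering needs at least 4 samples", call. = FALSE)
  if (drop_fraction <= 0) return(table)
  iqr <- apply(table$X, 2, stats::IQR)
  k <- floor(drop_fraction * ncol(table$X))
  if (k == 0L) return(table)
  drop <- order(iqr)[seq_len(k)]
  feature_table(table$X[, -drop, drop = FALSE], table$mz[-drop],
                table$classes)
}

#' Normalize each sample to unit total intensity
#'
#' @param table A [feature_table()] with positive row sums.
#' @return The row-normalized `feature_table`.
#' @export
sum_normalize <- function(table) {
  rs <- rowSums(table$X)
  if (any(rs <= 0))
    stop("sum normalization requires positive per-sample totals",
         call. = FALSE)
  feature_table(table$X / rs, table$mz, table$classes)
}

#' Pareto-scale features
#'
#' Centers each feature and divides by the square root of its standard
#' deviation, so the scaled variance equals the original standard deviation.
#' Zero-variance features are left centered and flagged in the
#' `zero_variance` attribute.
#'
#' @param table A [feature_table()].
#' @return The scaled `feature_table`.
#' @export
pareto_scale <- function(table) {
  s <- apply(table$X, 2, stats::sd)
  zero <- s == 0
  div <- ifelse(zero, 1, sqrt(s))
  Xs <- sweep(sweep(table$X, 2, colMeans(table$X)), 2, div, "/")
  out <- feature_table(Xs, table$mz, table$classes)
  attr(out, "zero_variance") <- which(zero)
  out
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis: NIPALS PLS2 regression of
#' the feature matrix against the one-hot class indicator matrix. Scores of
#' successive components are mutually orthogonal; prediction is the argmax
#' of the predicted class responses.
#'
#' @param table A preprocessed [feature_table()] with class labels (or a
#'   plain matrix, with `classes` supplied).
#' @param n_components Number of latent components.
#' @param classes Class labels when `table` is a matrix.
#' @param max_iter,tol NIPALS inner-loop controls.
#' @return An object of class `plsda`: scores `T`, loadings `P`, weights
#'   `W`, Y-loadings `Q`, regression coefficients `B`, centers, class
#'   levels, and `explained_x` variance fractions.
#' @export
plsda <- function(table, n_components = 2L, classes = NULL,
                  max_iter = 500L, tol = 1e-10) {
  if (inherits(table, "feature_table")) {
    X <- table$X
    if (is.null(classes)) classes <- table$classes
  } else X <- as.matrix(table)
  if (is.null(classes)) stop("class labels are required", call. = FALSE)
  classes <- factor(classes)
  if (nlevels(classes) < 2L)
    stop("PLS-DA needs at least 2 classes", call. = FALSE)
  Y <- stats::model.matrix(~ classes - 1)
  colnames(Y) <- levels(classes)
  if (n_components > qr(scale(X, scale = FALSE))$rank)
    stop("n_components exceeds the rank of the centered feature matrix",
         call. = FALSE)
  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center); Yc <- sweep(Y, 2, y_center)
  n <- nrow(Xc); p <- ncol(Xc); q <- n_components
  Tm <- matrix(0, n, q); W <- matrix(0, p, q); P <- matrix(0, p, q)
  Q <- matrix(0, ncol(Y), q)
  ssx_tot <- sum(Xc^2)
  explained <- numeric(q)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(q)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      qv <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% qv / sum(qv^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    pv <- crossprod(Xd, tt) / sum(tt^2)
    explained[a] <- sum(tt^2) * sum(pv^2) / ssx_tot
    Xd <- Xd - tt %*% t(pv)
    Yd <- Yd - tt %*% t(qv)
    Tm[, a] <- tt; W[, a] <- w; P[, a] <- pv; Q[, a] <- qv
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(
    list(T = Tm, W = W, P = P, Q = Q, B = B,
         x_center = x_center, y_center = y_center,
         levels = levels(classes), n_components = q,
         explained_x = explained, classes = classes),
    class = "plsda"
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", x$n_components, "components,",
      length(x$levels), "classes (", paste(x$levels, collapse = ", "), ")\n")
  cat("  X variance explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_x), collapse = " + "), "\n")
  invisible(x)
}

#' Predict classes from a PLS-DA model
#'
#' @param object A [plsda()] model.
#' @param newdata samples x features matrix or [feature_table()] on the same
#'   (preprocessed) feature space as the training data.
#' @param ... Unused.
#' @return List with `class` (factor) and `scores` (projections onto the
#'   latent components) and `response` (predicted indicator values).
#' @export
predict.plsda <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$X
    else as.matrix(newdata)
  Xc <- sweep(X, 2, object$x_center)
  resp <- sweep(Xc %*% object$B, 2, -object$y_center)
  colnames(resp) <- object$levels
  cls <- factor(object$levels[max.col(resp)], levels = object$levels)
  # scores via the X-weights accounting for deflation
  R <- object$W %*% solve(crossprod(object$P, object$W))
  list(class = cls, scores = Xc %*% R, response = resp)
}

#' Run the full point-sampling preprocessing chain
#'
#' Applies, in order: peak alignment (20 ppm), missing-value filtering
#' (> 80% missing removed), PPCA imputation, IQR filtering, per-spectrum sum
#' normalization and Pareto scaling. The executed step names are recorded in
#' the `steps` attribute of the result.
#'
#' @param spectra List of [spectrum()] objects.
#' @param classes Per-spectrum class labels.
#' @param tol_ppm Alignment tolerance, ppm.
#' @param max_missing Missing-fraction threshold.
#' @param ppca_components PPCA latent dimension (default
#'   `min(5, n_samples - 1)`).
#' @param iqr_drop_fraction Fraction of low-IQR features to drop.
#' @return A preprocessed [feature_table()] ready for [plsda()].
#' @export
preprocess_spectra <- function(spectra, classes = NULL, tol_ppm = 20,
                               max_missing = 0.80, ppca_components = NULL,
                               iqr_drop_fraction = 0.25) {
  steps <- character(0)
  tab <- align_features(spectra, classes, tol_ppm)
  steps <- c(steps, "align_features")
  tab <- filter_missing(tab, max_missing)
  steps <- c(steps, "filter_missing")
  tab <- impute_ppca(tab, ppca_components)
  steps <- c(steps, "impute_ppca")
  tab <- iqr_filter(tab, iqr_drop_fraction)
  steps <- c(steps, "iqr_filter")
  tab <- sum_normalize(tab)
  steps <- c(steps, "sum_normalize")
  tab <- pareto_scale(tab)
  steps <- c(steps, "pareto_scale")
  attr(tab, "steps") <- steps
  tab
}
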