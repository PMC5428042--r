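test_that("peak alignment merges within 20 ppm and splits beyond it", {
  s1 <- spectrum(c(391.250, 500.00), c(10, 4))
  s2 <- spectrum(c(391.253, 500.02), c(8, 5))      # 7.7 ppm and 40 ppm apart
  tab <- align_features(list(s1, s2))
  expect_equal(ncol(tab$X), 3L)                     # 391 merged, 500 split
  expect_equal(sum(!is.na(tab$X[, 1])), 2L)
  expect_error(align_features(list(s1)), "at least 2")
})

test_that("missing-value filter applies a strict 80% rule", {
  X <- matrix(1, 10, 3)
  X[1:9, 1] <- NA    # 90% missing -> dropped
  X[1:8, 2] <- NA    # exactly 80% -> retained
  tab <- filter_missing(feature_table(X, 1:3))
  expect_equal(tab$mz, c(2, 3))
  expect_identical(filter_missing(feature_table(matrix(1, 4, 2), 1:2))$X,
                   matrix(1, 4, 2))
  allna <- feature_table(matrix(NA_real_, 5, 2), 1:2)
  expect_error(filter_missing(allna), "threshold")
})

test_that("PPCA imputation restores low-rank structure and fixes observed cells", {
  set.seed(5)
  u <- stats::runif(20, 1, 2); v <- sort(stats::runif(30, 1, 5))
  X <- outer(u, v)
  Xm <- X
  idx <- sample(length(X), 60)                      # 10% of cells
  Xm[idx] <- NA
  tab <- feature_table(Xm, seq_len(30))
  imp <- impute_ppca(tab, n_components = 1)
  rel_rms <- sqrt(mean((imp$X[idx] - X[idx])^2)) / sqrt(mean(X[idx]^2))
  expect_lt(rel_rms, 0.01)
  expect_identical(imp$X[-idx], Xm[-idx])
  expect_true(attr(imp, "converged"))
  # deterministic (SVD-initialized EM, no randomness)
  expect_identical(impute_ppca(tab, n_components = 1)$X, imp$X)
  # complete tables pass through untouched
  full <- feature_table(X, seq_len(30))
  expect_identical(impute_ppca(full, 2)$X, X)
  expect_error(impute_ppca(tab, n_components = 25), "smaller")
})

test_that("IQR filtering drops the least variable features first", {
  set.seed(8)
  X <- cbind(matrix(stats::rexp(400), 20), rep(3, 20))  # constant last
  tab <- feature_table(X, 1:21)
  f <- iqr_filter(tab, 0.25)
  expect_equal(ncol(f$X), 16L)                       # floor(0.25*21)=5 dropped
  expect_false(21 %in% f$mz)                          # constant went first
  expect_identical(iqr_filter(tab, 0)$X, X)
  big <- feature_table(matrix(stats::rexp(400), 4), 1:100)
  expect_equal(ncol(iqr_filter(big, 0.25)$X), 75L)
  expect_error(iqr_filter(tab, 1), "< 1")
})

test_that("sum normalization and Pareto scaling satisfy their identities", {
  tab <- feature_table(rbind(c(2, 6), c(1, 3)), 1:2)
  sn <- sum_normalize(tab)
  expect_equal(sn$X[1, ], c(0.25, 0.75))
  expect_equal(unname(rowSums(sn$X)), c(1, 1))
  # var(pareto-scaled x) == sd(x)
  set.seed(3)
  Y <- matrix(stats::rexp(200, 0.3), 20, 10)
  ps <- pareto_scale(feature_table(Y, 1:10))
  expect_equal(apply(ps$X, 2, stats::var), apply(Y, 2, stats::sd),
               tolerance = 1e-12)
  # constant features are centered and flagged
  Z <- cbind(Y[, 1:2], rep(5, 20))
  pz <- pareto_scale(feature_table(Z, 1:3))
  expect_equal(unname(pz$X[, 3]), rep(0, 20))
  expect_identical(attr(pz, "zero_variance"), 3L)
  expect_error(sum_normalize(feature_table(rbind(c(0, 0), c(1, 1)), 1:2)),
               "positive")
})

test_that("PLS-DA separates linearly separable classes and validates input", {
  set.seed(11)
  X <- rbind(matrix(stats::rnorm(60, 0), 10),
             matrix(stats::rnorm(60, 4), 10))
  cls <- rep(c("a", "b"), each = 10)
  m <- plsda(X, n_components = 2, classes = cls)
  expect_identical(as.character(predict(m, X)$class), cls)
  expect_error(plsda(X, classes = rep("a", 20)), "2 classes")
  expect_error(plsda(X, n_components = 50, classes = cls), "rank")
})

test_that("PLS-DA scores are orthogonal and the first weight matches the SVD oracle", {
  set.seed(13)
  X <- matrix(stats::rnorm(90), 15, 6)
  cls <- rep(c("a", "b", "c"), each = 5)
  m <- plsda(X, n_components = 3, classes = cls)
  G <- crossprod(m$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # brute-force oracle: dominant right singular vector of Y'X
  Y <- stats::model.matrix(~ factor(cls) - 1)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  w_oracle <- svd(crossprod(Yc, Xc))$v[, 1]
  cossim <- abs(sum(w_oracle * m$W[, 1]))
  expect_equal(cossim, 1, tolerance = 1e-6)
})

test_that("four synthetic organ panels classify perfectly by leave-one-out", {
  fix <- organ_spectra()
  tab <- preprocess_spectra(fix$spectra, fix$classes)
  expect_identical(attr(tab, "steps"),
                   c("align_features", "filter_missing", "impute_ppca",
                     "iqr_filter", "sum_normalize", "pareto_scale"))
  m <- plsda(tab, n_components = 3)
  expect_identical(as.character(predict(m, tab)$class), fix$classes)
  hits <- vapply(seq_along(fix$spectra), function(i) {
    train <- feature_table(tab$X[-i, , drop = FALSE], tab$mz,
                           fix$classes[-i])
    fit <- plsda(train, n_components = 3)
    as.character(predict(fit, tab$X[i, , drop = FALSE])$class) ==
      fix$classes[i]
  }, logical(1))
  expect_equal(mean(hits), 1)
  # within-class score spread below between-class separation
  sc <- predict(m, tab)$scores
  cent <- rowsum(sc, fix$classes) / 6
  within <- mean(sqrt(rowSums((sc - cent[fix$classes, ])^2)))
  between <- mean(stats::dist(cent))
  expect_lt(within, between)
})

test_that("this package's PLS-DA agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  fix <- organ_spectra()
  tab <- preprocess_spectra(fix$spectra, fix$classes)
  X <- tab$X
  colnames(X) <- sprintf("mz%.4f", tab$mz)
  ref <- mixOmics::plsda(X, factor(fix$classes), ncomp = 3, scale = FALSE)
  ref_pred <- predict(ref, X)$class$max.dist[, 3]
  ours <- as.character(predict(plsda(tab, 3), tab)$class)
  expect_identical(ours, unname(ref_pred))
  # leading latent direction agrees up to sign
  w_ref <- ref$loadings$X[, 1]
  fit <- plsda(tab, 3)
  expect_equal(abs(sum(w_ref * fit$W[, 1])), 1, tolerance = 1e-6)
})
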