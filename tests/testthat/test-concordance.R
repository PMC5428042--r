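ms_fixture <- function(class = "necrotic", n = 32L, seed = 3L) {
  tic_normalize(simulate_desi(uniform_label_map(class, n, 100), seed = seed))
}

test_that("TIC normalization is exact, idempotent and flags zero-TIC spectra", {
  img <- structure(
    list(spectra = list(spectrum(c(300, 400), c(2, 6))),
         dim = c(1L, 1L), pixel_pitch_um = 100, origin_um = c(0, 0),
         raster = list(stage_speed_um_s = 100, integration_s = 1),
         normalized = FALSE),
    class = "ms_image")
  n1 <- tic_normalize(img)
  expect_equal(n1$spectra[[1]]$intensity, c(0.25, 0.75))
  n2 <- tic_normalize(n1)
  expect_equal(n2$spectra[[1]]$intensity, c(0.25, 0.75))
  sums <- vapply(ms_fixture()$spectra, function(s) sum(s$intensity),
                 numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
  img$spectra[[1]]$intensity <- c(0, 0)
  expect_warning(nz <- tic_normalize(img), "zero-TIC")
  expect_true(all(is.na(nz$spectra[[1]]$intensity)))
})

test_that("ion images sum in-window relative intensities", {
  img <- structure(
    list(spectra = list(
      spectrum(c(572.478, 572.484, 300), c(0.25, 0.20, 0.55)),
      spectrum(c(400), c(1))),
      dim = c(1L, 2L), pixel_pitch_um = 100, origin_um = c(0, 0),
      raster = list(stage_speed_um_s = 100, integration_s = 1),
      normalized = TRUE),
    class = "ms_image")
  ii <- ion_image(img, 572.48, 20)
  expect_equal(ii$values[1, 1], 0.45)   # two in-window peaks summed
  expect_equal(ii$values[1, 2], 0)
  expect_true(all(ii$values <= 1))
  absent <- ion_image(img, 650.0, 20)
  expect_true(all(absent$values == 0))
  img$normalized <- FALSE
  expect_error(ion_image(img, 572.48), "TIC-normalized")
})

test_that("ROI statistics reproduce the marker fold-change bands", {
  dm <- structure(
    list(values = matrix(0.35, 20, 20), metric = "depolarization",
         geometry = "transmission", pixel_size_um = 100),
    class = "depolarization_map")
  r <- roi(c(1600, 1600), 3200, 3200, "necrotic")
  folds_nec <- vapply(4:6, function(s) {
    nec <- ms_fixture("necrotic", seed = s)
    roi_stats(list(viable = ion_image(nec, 391.25),
                   necrotic = ion_image(nec, 572.48)), dm, r)$fold
  }, numeric(1))
  expect_gte(mean(folds_nec), 5); expect_lte(mean(folds_nec), 6)
  dmv <- dm; dmv$values[] <- 0.20
  rv <- roi(c(1600, 1600), 3200, 3200, "viable")
  folds_via <- vapply(4:6, function(s) {
    via <- ms_fixture("viable", seed = s)
    roi_stats(list(viable = ion_image(via, 391.25),
                   necrotic = ion_image(via, 572.48)), dmv, rv)$fold
  }, numeric(1))
  expect_gte(mean(folds_via), 3); expect_lte(mean(folds_via), 4)
  # identical marker means give fold 1
  nec <- ms_fixture("necrotic", seed = 5)
  same <- list(viable = ion_image(nec, 572.48),
               necrotic = ion_image(nec, 572.48))
  expect_equal(roi_stats(same, dm, r)$fold, 1.0)
  # ROI outside the frame errors
  expect_error(roi_stats(list(viable = ion_image(nec, 391.25),
                              necrotic = ion_image(nec, 572.48)),
                         dm, roi(c(9e5, 9e5), 1000, 1000, "viable")),
               "outside")
})

test_that("fold changes are invariant to global intensity rescaling", {
  raw <- simulate_desi(uniform_label_map("necrotic", 15L, 100), seed = 9)
  scaled <- raw
  scaled$spectra <- lapply(scaled$spectra, function(s) {
    s$intensity <- s$intensity * 137.5
    s
  })
  dm <- structure(
    list(values = matrix(0.35, 15, 15), metric = "depolarization",
         geometry = "transmission", pixel_size_um = 100),
    class = "depolarization_map")
  r <- roi(c(750, 750), 1400, 1400, "necrotic")
  f <- function(img) {
    n <- tic_normalize(img)
    roi_stats(list(viable = ion_image(n, 391.25),
                   necrotic = ion_image(n, 572.48)), dm, r)$fold
  }
  expect_equal(f(raw), f(scaled))
})

test_that("depolarization histograms use 2.5-point bins with lower-tie modes", {
  expect_equal(hist_mode(c(34, 34.2, 36.4, 20), 2.5), 33.75)
  # tie between two bins resolves to the lower one
  expect_equal(hist_mode(c(1, 1.2, 26, 26.2), 2.5), 1.25)
  expect_true(is.na(hist_mode(numeric(0), 2.5)))
})

test_that("concordance verdicts compare polarimetric class with dominant marker", {
  mk <- function(hyp, depol, mv, mn) {
    list(hypothesis = hyp, marker_means = c(viable = mv, necrotic = mn),
         fold = max(mv, mn) / min(mv, mn), fold_markers = "x",
         intensity_hist = NULL, depol_hist = NULL,
         depol_mode_pct = depol, depol_mean_pct = depol,
         n_ms_pixels = 100L, n_depol_pixels = 100L)
  }
  ok <- concordance_summary(list(
    mk("necrotic", 35, 0.05, 0.40),
    mk("viable", 20, 0.33, 0.10),
    mk("border", 27.5, 0.15, 0.15)))
  expect_equal(attr(ok, "fraction_concordant"), 1)
  # swapped marker profile in a necrotic ROI -> discordant
  bad <- concordance_summary(list(mk("necrotic", 35, 0.40, 0.05)))
  expect_identical(bad$verdict, "discordant")
  # empty report -> empty table
  empty <- concordance_summary(list())
  expect_identical(nrow(empty), 0L)
})
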