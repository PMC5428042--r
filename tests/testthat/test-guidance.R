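test_that("rigid fits recover exact transforms and degenerate input errors", {
  pts <- cbind(c(0, 25000, 25000, 0), c(0, 0, 75000, 75000))  # slide corners
  tf0 <- fit_rigid(pts, pts)
  expect_equal(tf0$rotation_rad, 0)
  expect_equal(tf0$translation_um, c(0, 0))
  expect_equal(tf0$rms, 0)
  tft <- fit_rigid(pts, sweep(pts, 2, -c(500, -300)))
  expect_equal(tft$rotation_rad, 0)
  expect_equal(tft$translation_um, c(500, -300))
  expect_equal(tft$rms, 0, tolerance = 1e-9)
  expect_error(fit_rigid(pts[1, , drop = FALSE], pts[1, , drop = FALSE]),
               "at least 2")
  expect_error(fit_rigid(rbind(c(1, 1), c(1, 1)), rbind(c(0, 0), c(2, 2))),
               "coincident")
})

test_that("a 10-degree rotation about the centroid is recovered to 1e-9", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)) * 1000
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- colMeans(sq)
  dst <- sweep(sweep(sq, 2, ctr) %*% t(R), 2, -ctr)
  tf <- fit_rigid(sq, dst)
  expect_lt(abs(tf$rotation_rad - th), 1e-9)
})

test_that("rigid fitting is inverse-consistent on random constructed transforms", {
  set.seed(9)
  for (i in 1:20) {
    src <- matrix(stats::runif(10, 0, 2e4), ncol = 2)
    th <- stats::runif(1, -pi, pi)
    t_um <- stats::runif(2, -5e3, 5e3)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    dst <- sweep(src %*% t(R), 2, -t_um)
    fwd <- fit_rigid(src, dst)
    bwd <- fit_rigid(dst, src)
    inv <- invert_transform(fwd)
    expect_lt(abs(fwd$rotation_rad - th), 1e-9)
    expect_lt(abs(bwd$rotation_rad - inv$rotation_rad), 1e-9)
    expect_lt(max(abs(bwd$translation_um - inv$translation_um)), 1e-6)
    # transforms round-trip points
    expect_lt(max(abs(apply_transform(inv, apply_transform(fwd, src)) - src)),
              1e-6)
  }
})

test_that("scan timing follows the pixel-count model", {
  r1 <- roi(c(5000, 5000), 1000, 1000, "viable")
  plan1 <- scan_plan(list(r1))
  expect_equal(plan1$n_pixels, 100)        # 10 x 10 grid at 100 um
  expect_equal(scan_time(plan1), 100)      # 1 s per pixel
  # additivity over disjoint ROIs
  r2 <- roi(c(12000, 5000), 2000, 2000, "necrotic")
  expect_equal(scan_time(scan_plan(list(r1, r2))),
               scan_time(plan1) + scan_time(scan_plan(list(r2))))
  expect_equal(speedup(c(17000, 17000), scan_plan(list(r1, r2))),
               28900 / 500)
})

test_that("guided acquisition of the reference 8-ROI set is >20x faster", {
  sizes <- c(rep(1, 6), rep(4, 2)) * 1e6   # um^2
  rois <- lapply(seq_along(sizes), function(k)
    roi(c(3000 * k, 3000), sqrt(sizes[k]), sqrt(sizes[k]),
        c("necrotic", "viable")[k %% 2 + 1]))
  plan <- scan_plan(rois)
  expect_equal(plan$n_pixels, 1400)
  f <- speedup(c(17000, 17000), plan)
  expect_equal(f, 28900 / 1400)
  expect_gt(f, 20)
  # full field equal to target -> speedup 1
  full <- scan_plan(list(roi(c(8500, 8500), 17000, 17000, "border")))
  expect_equal(speedup(c(17000, 17000), full), 1.0)
})

test_that("boundary mismatch is zero for identical masks and exact for pure shifts", {
  mask <- matrix(FALSE, 60, 60)
  mask[20:40, ] <- TRUE                     # full-width band
  expect_equal(boundary_mismatch(mask, mask, 17)$mean_um, 0)
  shifted <- matrix(FALSE, 60, 60)
  shifted[21:41, ] <- TRUE                  # one-pixel shift: 17 um
  mm <- boundary_mismatch(mask, shifted, 17, align = FALSE)
  expect_equal(mm$mean_um, 17, tolerance = 0.15)
  expect_error(boundary_mismatch(mask, matrix(FALSE, 60, 60), 17),
               "non-empty")
})

test_that("proposed ROIs are deterministic, non-overlapping and correctly labelled", {
  map <- make_label_map(n_px = c(250L, 250L), pixel_size_um = 68, seed = 2)
  dm <- depol_roundtrip(map, seed = 12)
  rois <- propose_rois(dm)
  rois2 <- propose_rois(dm)
  expect_identical(rois, rois2)
  expect_length(rois, 8L)
  expect_equal(sum(vapply(rois, function(r)
    r$width_um * r$height_um, numeric(1))) / 1e6, 14)
  expect_setequal(unique(vapply(rois, function(r) r$hypothesis,
                                character(1))),
                  c("necrotic", "viable", "border"))
  # non-overlap
  for (i in seq_along(rois)) for (j in seq_len(i - 1L)) {
    a <- rois[[i]]; b <- rois[[j]]
    sep <- abs(a$center_um - b$center_um)
    expect_true(sep[1] >= (a$width_um + b$width_um) / 2 - 1e-9 ||
                  sep[2] >= (a$height_um + b$height_um) / 2 - 1e-9)
  }
})

test_that("ROI hypotheses match the ground-truth majority class", {
  correct <- 0L; total <- 0L
  for (s in 1:3) {
    map <- make_label_map(n_px = c(250L, 250L), pixel_size_um = 68, seed = s)
    dm <- depol_roundtrip(map, seed = 20 + s)
    rois <- propose_rois(dm)
    px <- map$pixel_size_um
    for (r in rois) {
      if (r$hypothesis == "border") next
      j <- round(r$center_um[1] / px); i <- round(r$center_um[2] / px)
      h <- ceiling(r$width_um / px / 2)
      block <- map$labels[max(1, i - h):min(nrow(map$labels), i + h),
                          max(1, j - h):min(ncol(map$labels), j + h)]
      gt <- tissue_classes()[as.integer(names(which.max(table(block)))) + 1L]
      total <- total + 1L
      if (gt == r$hypothesis) correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 7 / 8)
})

test_that("a uniform depolarization map cannot seed ROIs", {
  flat <- structure(
    list(values = matrix(0.3, 50, 50), metric = "depolarization",
         geometry = "transmission", pixel_size_um = 68),
    class = "depolarization_map")
  expect_error(propose_rois(flat), "uniform")
})
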