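#' Construct a 2-D rigid transform (rotation + translation, no scale)
#'
#' @param rotation_rad Rotation angle in radians (counter-clockwise).
#' @param translation_um Length-2 numeric `c(tx, ty)` in micrometres.
#' @param rms Optional fit residual RMS (um).
#' @return An object of class `rigid_transform_2d`.
#' @export
rigid_transform <- function(rotation_rad = 0, translation_um = c(0, 0),
                            rms = NA_real_) {
  structure(list(rotation_rad = rotation_rad,
                 translation_um = translation_um, rms = rms),
            class = "rigid_transform_2d")
}

#' @export
print.rigid_transform_2d <- function(x, ...) {
  cat(sprintf("Rigid 2D transform: rotation %.6f rad, translation (%.2f, %.2f) um",
              x$rotation_rad, x$translation_um[1], x$translation_um[2]))
  if (!is.na(x$rms)) cat(sprintf(", fit RMS %.3g um", x$rms))
  cat("\n")
  invisible(x)
}

.rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Apply a rigid transform to points
#' @param tf A [rigid_transform()].
#' @param pts n x 2 matrix of (x, y) coordinates in micrometres.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(tf, pts) {
  pts <- matrix(pts, ncol = 2)
  sweep(pts %*% t(.rot2(tf$rotation_rad)), 2, -tf$translation_um)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @return The inverse `rigid_transform_2d`.
#' @export
invert_transform <- function(tf) {
  Rinv <- .rot2(-tf$rotation_rad)
  rigid_transform(-tf$rotation_rad,
                  as.numeric(-Rinv %*% tf$translation_um), tf$rms)
}

#' Least-squares rigid registration of point pairs
#'
#' Two-dimensional orthogonal Procrustes fit without scaling or reflection
#' (Kabsch algorithm): finds the rotation and translation mapping `src` onto
#' `dst` with minimal sum of squared residuals. The canonical use is the
#' four slide-corner fiducials that tie the optical/polarimetry frame to the
#' MS stage frame.
#'
#' @param src,dst n x 2 matrices of matched (x, y) points, micrometres.
#' @return A [rigid_transform()] with the residual RMS recorded.
#' @export
fit_rigid <- function(src, dst) {
  src <- matrix(src, ncol = 2); dst <- matrix(dst, ncol = 2)
  if (nrow(src) < 2L || nrow(dst) != nrow(src))
    stop("at least 2 matched point pairs are required", call. = FALSE)
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  if (max(abs(A)) == 0)
    stop("source points are coincident; the rotation is undefined",
         call. = FALSE)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  theta <- atan2(R[2, 1], R[1, 1])
  t_um <- cd - as.numeric(R %*% cs)
  res <- sweep(A %*% t(R), 2, -cd) - dst
  rigid_transform(theta, t_um, sqrt(mean(rowSums(res^2))))
}

#' Construct a region of interest on the MS stage
#'
#' @param center_um Stage coordinates `c(x, y)` of the ROI center,
#'   micrometres.
#' @param width_um,height_um ROI extent in micrometres.
#' @param hypothesis Tissue hypothesis: `"necrotic"`, `"viable"` or
#'   `"border"`.
#' @return An object of class `roi`.
#' @export
roi <- function(center_um, width_um, height_um,
                hypothesis = c("necrotic", "viable", "border")) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(width_um > 0, height_um > 0)
  structure(list(center_um = center_um, width_um = width_um,
                 height_um = height_um, hypothesis = hypothesis),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI (%s): center (%.0f, %.0f) um, %.0f x %.0f um\n",
              x$hypothesis, x$center_um[1], x$center_um[2],
              x$width_um, x$height_um))
  invisible(x)
}

# greedy placement of one ROI class over a score map; ROIs keep the exact
# requested physical size, the pixel grid only drives the search
.place_rois <- function(score, eligible, sizes_um, taken, pixel_size_um,
                        hypothesis, frac_min = 0.6) {
  H <- nrow(score); W <- ncol(score)
  ord <- order(score, decreasing = TRUE, na.last = NA)
  ord <- ord[eligible[ord]]
  out <- list()
  for (side_um in sizes_um) {
    hw <- as.integer(ceiling(side_um / 2 / pixel_size_um))
    placed <- FALSE
    for (p in ord) {
      i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
      i1 <- i - hw; i2 <- i + hw; j1 <- j - hw; j2 <- j + hw
      if (i1 < 1L || j1 < 1L || i2 > H || j2 > W) next
      if (any(taken[i1:i2, j1:j2])) next
      frac <- mean(eligible[i1:i2, j1:j2], na.rm = TRUE)
      if (is.na(frac) || frac < frac_min) next
      taken[i1:i2, j1:j2] <- TRUE
      out[[length(out) + 1L]] <-
        roi(c((j - 0.5) * pixel_size_um, (i - 0.5) * pixel_size_um),
            side_um, side_um, hypothesis)
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  list(rois = out, taken = taken)
}

#' Propose targeted ROIs from a depolarization map
#'
#' Splits the depolarization histogram with Otsu's threshold; necrotic ROIs
#' are seeded at local maxima above the upper margin, viable ROIs below the
#' lower margin, and border ROIs on the high-gradient band between the two.
#' ROIs are square, non-overlapping and restricted to regions dominated by
#' their target band. Default request reproduces the guided-acquisition
#' configuration of 8 ROIs (six of 1 mm2 plus two of 4 mm2, 14 mm2 total).
#'
#' @param map A [depolarization_map()] (metric `"depolarization"`).
#' @param n_necrotic,n_viable,n_border Requested ROI counts per hypothesis.
#' @param sizes_mm2 Optional named list of per-class ROI areas (mm2),
#'   `list(necrotic = ..., viable = ..., border = ...)`. By default each
#'   class gets 1 mm2 ROIs, except that the last necrotic and last viable
#'   ROI are 4 mm2 when three or more of that class are requested.
#' @param margin Half-width (depolarization units) of the border band around
#'   the Otsu split, also added to the split for the necrotic/viable
#'   thresholds.
#' @param smooth_sigma_px Gaussian smoothing applied before seeding.
#' @return List of [roi()] objects; a warning is raised when fewer ROIs than
#'   requested could be placed.
#' @export
propose_rois <- function(map, n_necrotic = 3L, n_viable = 3L, n_border = 2L,
                         sizes_mm2 = NULL, margin = 0.05,
                         smooth_sigma_px = 2) {
  v <- map$values
  val <- v[!is.na(v)]
  if (!length(val)) stop("map has no valid pixels", call. = FALSE)
  if (stats::sd(val) < 1e-6)
    stop("map is uniform: no depolarization contrast to seed border or ",
         "class ROIs", call. = FALSE)
  if (is.null(sizes_mm2)) {
    sz <- function(n) if (n >= 3L) c(rep(1, n - 1L), 4) else rep(1, n)
    sizes_mm2 <- list(necrotic = sz(n_necrotic), viable = sz(n_viable),
                      border = rep(1, n_border))
  }
  sm <- v
  sm[is.na(sm)] <- stats::median(val)
  if (smooth_sigma_px > 0) sm <- EBImage::gblur(sm, sigma = smooth_sigma_px)
  sm[is.na(v)] <- NA
  # Thresholds are taken on the smoothed map, where the pixel noise is
  # averaged out and the class populations separate. Healthy tissue can be
  # even more depolarizing than necrotic tumour, so the histogram may be
  # trimodal: fit 2- and 3-class Otsu splits, and when three well-populated
  # classes explain clearly more between-class variance, take the middle
  # class as the necrotic band and exclude the hyper-depolarizing top class.
  sp <- .otsu_multi(sm[!is.na(sm)])
  if (length(sp) == 2L) {
    border_center <- sp[1]
    necro_band <- c(sp[1] + margin, sp[2] - margin)
  } else {
    border_center <- sp[1]
    necro_band <- c(sp[1] + margin, Inf)
  }
  gx <- cbind(sm[, -1] - sm[, -ncol(sm)], 0)
  gy <- rbind(sm[-1, ] - sm[-nrow(sm), ], 0)
  grad <- sqrt(gx^2 + gy^2)

  taken <- matrix(FALSE, nrow(v), ncol(v))
  rois <- list()
  place <- function(score, eligible, sizes, hyp, frac_min = 0.6) {
    # large ROIs first so small ones cannot fragment the available region
    sizes <- sort(sizes, decreasing = TRUE)
    r <- .place_rois(score, eligible & !is.na(v),
                     vapply(sizes, function(a) sqrt(a) * 1000, numeric(1)),
                     taken, map$pixel_size_um, hyp, frac_min)
    taken <<- r$taken
    rois <<- c(rois, r$rois)
    length(r$rois) == length(sizes)
  }
  ok_n <- place(sm, sm > necro_band[1] & sm <= necro_band[2],
                sizes_mm2$necrotic, "necrotic", frac_min = 0.7)
  ok_v <- place(-sm, sm < border_center - margin, sizes_mm2$viable,
                "viable", frac_min = 0.7)
  # a border ROI straddles the viable/necrotic interface: its center sits on
  # the thin high-gradient band (which cannot fill the square, so only a
  # small eligible fraction is required) and must have both viable-band and
  # necrotic-band tissue nearby -- a mid-level value on the boundary to an
  # excluded hyper-depolarizing region does not qualify
  # smoothing ramps at any interface pass through intermediate values, so a
  # morphological opening first removes thin ramp artifacts: only extended
  # regions genuinely in a band count as that tissue
  br_open <- EBImage::makeBrush(7L, "disc")
  br_near <- EBImage::makeBrush(15L, "disc")
  near_region <- function(mask) {
    m <- mask; m[is.na(m)] <- FALSE
    opened <- EBImage::opening(m, br_open)
    EBImage::dilate(opened, br_near) > 0
  }
  straddle <- abs(sm - border_center) <= margin &
    near_region(sm > necro_band[1] & sm <= necro_band[2]) &
    near_region(sm < border_center - margin)
  ok_b <- place(grad, straddle, sizes_mm2$border, "border", frac_min = 0.08)
  if (!(ok_n && ok_v && ok_b))
    warning("could not place all requested ROIs; returning ",
            length(rois), " of ",
            n_necrotic + n_viable + n_border, call. = FALSE)
  rois
}

# 2- vs 3-class Otsu model choice: returns one threshold (2-class) or two
# (3-class). The 3-class split is kept only when every class holds at least
# 5% of the pixels and it improves the between-class variance by >5%
# (measured bimodal maps sit below ~3% improvement, trimodal above ~7%).
.otsu_multi <- function(x, levels = 128L) {
  r <- range(x)
  h <- tabulate(pmin(levels, 1L + floor((x - r[1]) / diff(r) * levels)),
                levels)
  p <- h / sum(h)
  centers <- r[1] + (seq_len(levels) - 0.5) * diff(r) / levels
  cw <- cumsum(p); cm <- cumsum(p * centers)
  mu_t <- cm[levels]
  # best 2-class split
  sb2 <- (mu_t * cw - cm)^2 / (cw * (1 - cw))
  sb2[!is.finite(sb2)] <- 0
  k2 <- which.max(sb2)
  best2 <- sb2[k2]
  # best 3-class split (exhaustive over threshold pairs)
  best3 <- -Inf; k3 <- c(NA_integer_, NA_integer_)
  for (i in seq_len(levels - 2L)) {
    w1 <- cw[i]
    if (w1 < 0.05) next
    m1 <- cm[i]
    j <- (i + 1L):(levels - 1L)
    w2 <- cw[j] - w1; w3 <- 1 - cw[j]
    ok <- w2 >= 0.05 & w3 >= 0.05
    if (!any(ok)) next
    m2 <- cm[j] - m1; m3 <- mu_t - cm[j]
    v <- ifelse(ok,
                m1^2 / w1 + m2^2 / w2 + m3^2 / w3 - mu_t^2,
                -Inf)
    jb <- which.max(v)
    if (v[jb] > best3) { best3 <- v[jb]; k3 <- c(i, j[jb]) }
  }
  v2 <- best2
  v3 <- best3
  # express 2-class criterion on the same scale
  v2 <- cm[k2]^2 / cw[k2] + (mu_t - cm[k2])^2 / (1 - cw[k2]) - mu_t^2
  if (is.finite(v3) && v3 > 1.05 * v2) centers[k3] else centers[k2]
}

# Otsu threshold on a numeric vector (256 bins over the data range)
.otsu <- function(x, levels = 256L) {
  r <- range(x)
  h <- tabulate(pmin(levels, 1L + floor((x - r[1]) / diff(r) * levels)),
                levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- r[1] + (seq_len(levels) - 0.5) * diff(r) / levels
  mu <- cumsum(p * centers)
  mu_t <- mu[levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  centers[which.max(sb2)]
}

#' Build a targeted raster scan plan
#'
#' @param rois List of [roi()] objects.
#' @param pixel_pitch_um Raster pitch, micrometres.
#' @param integration_s Integration time per pixel, seconds. At the default
#'   100 um/s stage speed and 100 um pitch the pixel dwell equals the
#'   integration time.
#' @param stage_speed_um_s Stage speed, micrometres per second.
#' @return An object of class `scan_plan` with `n_pixels` and
#'   `estimated_time_s`.
#' @export
scan_plan <- function(rois, pixel_pitch_um = 100, integration_s = 1,
                      stage_speed_um_s = 100) {
  if (!length(rois)) stop("empty scan plan", call. = FALSE)
  npx <- vapply(rois, function(r)
    max(1L, floor(r$width_um / pixel_pitch_um)) *
      max(1L, floor(r$height_um / pixel_pitch_um)), numeric(1))
  structure(
    list(rois = rois, pixel_pitch_um = pixel_pitch_um,
         integration_s = integration_s, stage_speed_um_s = stage_speed_um_s,
         n_pixels = sum(npx),
         estimated_time_s = sum(npx) * integration_s),
    class = "scan_plan"
  )
}

#' @export
print.scan_plan <- function(x, ...) {
  cat("Scan plan:", length(x$rois), "ROIs,", x$n_pixels, "pixels,",
      x$estimated_time_s, "s estimated\n")
  invisible(x)
}

#' Estimated acquisition time of a scan plan
#' @param plan A [scan_plan()].
#' @return Seconds.
#' @export
scan_time <- function(plan) plan$estimated_time_s

#' Fold speed-up of a targeted plan over untargeted full-field imaging
#'
#' @param full_region_um Length-2 `c(width_um, height_um)` of the full field.
#' @param plan A [scan_plan()].
#' @return Fold reduction in acquisition time (full-field pixels divided by
#'   targeted pixels).
#' @export
speedup <- function(full_region_um, plan) {
  full_px <- floor(full_region_um[1] / plan$pixel_pitch_um) *
    floor(full_region_um[2] / plan$pixel_pitch_um)
  if (plan$n_pixels == 0) stop("zero targeted area", call. = FALSE)
  full_px / plan$n_pixels
}

# boundary pixels of a logical mask (4-connectivity); masks clipped by the
# canvas edge contribute no contour there
.boundary_points <- function(mask, pixel_size_um) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(TRUE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  idx <- which(mask & !inner)
  i <- (idx - 1L) %% H + 1L; j <- (idx - 1L) %/% H + 1L
  cbind(x = (j - 0.5) * pixel_size_um, y = (i - 0.5) * pixel_size_um)
}

# rigid transform aligning mask B onto mask A from centroid + principal axis
.moment_align <- function(mask_a, mask_b, pixel_size_um) {
  feat <- function(m) {
    idx <- which(m)
    i <- (idx - 1L) %% nrow(m) + 1L; j <- (idx - 1L) %/% nrow(m) + 1L
    P <- cbind((j - 0.5) * pixel_size_um, (i - 0.5) * pixel_size_um)
    ctr <- colMeans(P)
    C <- stats::cov(P)
    ev <- eigen(C, symmetric = TRUE)
    list(ctr = ctr, theta = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
  }
  fa <- feat(mask_a); fb <- feat(mask_b)
  dth <- fa$theta - fb$theta
  dth <- atan2(sin(dth), cos(dth))
  if (dth > pi / 2) dth <- dth - pi
  if (dth < -pi / 2) dth <- dth + pi
  R <- .rot2(dth)
  rigid_transform(dth, fa$ctr - as.numeric(R %*% fb$ctr))
}

#' Symmetric mean nearest-boundary distance between two masks
#'
#' Measures the internal-border mismatch between two binary masks (e.g. the
#' viable-cancer region of two serial sections). Mask B is first rigidly
#' aligned to mask A using centroids and principal axes (disable with
#' `align = FALSE`), then the mean and 95th percentile of nearest-neighbour
#' distances between the two boundary point sets are reported, symmetrized
#' over both directions.
#'
#' @param mask_a,mask_b Logical H x W matrices (same grid).
#' @param pixel_size_um Pixel size, micrometres.
#' @param align Apply rigid pre-alignment before measuring.
#' @param max_points Per-mask cap on boundary points (subsampled beyond it).
#' @return List with `mean_um` and `p95_um`.
#' @export
boundary_mismatch <- function(mask_a, mask_b, pixel_size_um = 17,
                              align = TRUE, max_points = 1500L) {
  if (!any(mask_a) || !any(mask_b))
    stop("both masks must be non-empty", call. = FALSE)
  pa <- .boundary_points(mask_a, pixel_size_um)
  pb <- .boundary_points(mask_b, pixel_size_um)
  if (align) {
    tf <- .moment_align(mask_a, mask_b, pixel_size_um)
    pb <- apply_transform(tf, pb)
  }
  sub <- function(p) {
    if (nrow(p) > max_points)
      p[round(seq(1, nrow(p), length.out = max_points)), , drop = FALSE]
    else p
  }
  pa <- sub(pa); pb <- sub(pb)
  D <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  d <- c(apply(D, 1, min), apply(D, 2, min))
  list(mean_um = mean(d), p95_um = unname(stats::quantile(d, 0.95)))
}
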