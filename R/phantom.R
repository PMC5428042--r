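#' Tissue classes used by the phantom generator
#' @return Character vector of class names, in label order (label 0 =
#'   background).
#' @export
tissue_classes <- function() c("background", "muscle", "viable", "necrotic")

#' Polarimetric and rendering parameters per tissue class
#'
#' Defaults encode the depolarization contrast of a breast-tumour xenograft:
#' viable cancer is weakly depolarizing (mean 0.20), necrotic cancer more so
#' (mean 0.35), and healthy muscle more depolarizing than both (mean 0.50).
#' Background pixels carry no signal and are invalid. Reflection-mode
#' rendering degrades the map with Gaussian blur and contrast compression,
#' reproducing the lower resolution and contrast of thick-tissue imaging.
#'
#' @param depol_mean Named numeric vector of class mean depolarization.
#' @param depol_sd Named numeric vector of class depolarization standard
#'   deviations (truncated so mean +/- 3 sd stays inside `[0, 1]`).
#' @param reflection_contrast_scale Multiplicative contrast compression
#'   applied to the depolarization field in reflection geometry.
#' @param reflection_blur_sigma_um Gaussian blur standard deviation (um)
#'   applied in reflection geometry.
#' @return An object of class `tissue_class_model`.
#' @export
tissue_class_model <- function(
    depol_mean = c(muscle = 0.50, viable = 0.20, necrotic = 0.35),
    depol_sd = c(muscle = 0.05, viable = 0.05, necrotic = 0.05),
    reflection_contrast_scale = 0.5,
    reflection_blur_sigma_um = 100) {
  for (cl in names(depol_mean)) {
    lo <- depol_mean[[cl]] - 3 * depol_sd[[cl]]
    hi <- depol_mean[[cl]] + 3 * depol_sd[[cl]]
    if (lo < 0 || hi > 1)
      stop("class '", cl, "': depol_mean +/- 3 sd must lie in [0, 1]",
           call. = FALSE)
  }
  structure(
    list(depol_mean = depol_mean, depol_sd = depol_sd,
         reflection_contrast_scale = reflection_contrast_scale,
         reflection_blur_sigma_um = reflection_blur_sigma_um),
    class = "tissue_class_model"
  )
}

#' Generate a ground-truth tissue label map
#'
#' Emulates a tumour-infiltrated tissue slice: an elliptical tumour with a
#' necrotic core and a viable rim, embedded in a band of healthy muscle, on a
#' clear background. Region boundaries get a small seeded sinusoidal wobble
#' so that different seeds give different (but statistically equivalent)
#' morphologies. The default 1000 x 1000 px canvas at 17 um/px matches a
#' 1.7 cm x 1.7 cm polarimetry field of view.
#'
#' @param n_px Integer `c(H, W)` canvas size in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param tissue_frac,tumour_frac,necrotic_frac Semi-axis of the muscle,
#'   tumour (viable + necrotic) and necrotic-core ellipses as a fraction of
#'   the smaller canvas dimension. Set `necrotic_frac = 0` for a phantom
#'   without necrosis.
#' @param wobble Relative amplitude of the seeded boundary irregularity.
#' @param seed Integer seed; identical seeds give identical maps.
#' @return An object of class `label_map`: list with `labels` (integer H x W
#'   matrix, 0 = background, 1 = muscle, 2 = viable, 3 = necrotic),
#'   `pixel_size_um` and `classes`.
#' @export
make_label_map <- function(n_px = c(1000L, 1000L), pixel_size_um = 17,
                           tissue_frac = 0.36, tumour_frac = 0.30,
                           necrotic_frac = 0.12, wobble = 0.04, seed = 1L) {
  if (tissue_frac > 0.5 || tumour_frac > tissue_frac ||
      necrotic_frac > tumour_frac)
    stop("region geometry exceeds the canvas or is not nested", call. = FALSE)
  set.seed(seed)
  H <- n_px[1]; W <- n_px[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r0 <- min(H, W)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  th <- atan2(yy, xx)
  rr <- sqrt(yy^2 + xx^2)
  # seeded low-order harmonic wobble per boundary
  wob <- function(amp) {
    k <- sample(2:5, 2)
    ph <- stats::runif(2, 0, 2 * pi)
    a <- stats::runif(2, 0.3, 1) * amp
    1 + a[1] * cos(k[1] * th + ph[1]) + a[2] * cos(k[2] * th + ph[2])
  }
  labels <- matrix(0L, H, W)
  labels[rr <= tissue_frac * r0 * wob(wobble)] <- 1L           # muscle
  labels[rr <= tumour_frac * r0 * wob(wobble)] <- 2L           # viable rim
  if (necrotic_frac > 0)
    labels[rr <= necrotic_frac * r0 * wob(wobble)] <- 3L       # necrotic core
  structure(
    list(labels = labels, pixel_size_um = pixel_size_um,
         classes = tissue_classes()),
    class = "label_map"
  )
}

#' Uniform single-class label map
#'
#' Convenience constructor for a rectangular region made of one tissue
#' class, e.g. the interior of a targeted ROI.
#'
#' @param class One of [tissue_classes()].
#' @param n_px Integer `c(H, W)` (a scalar is used for both).
#' @param pixel_size_um Pixel size in micrometres.
#' @return A `label_map`.
#' @export
uniform_label_map <- function(class, n_px = 118L, pixel_size_um = 17) {
  lev <- match(class, tissue_classes()) - 1L
  if (is.na(lev)) stop("unknown class: ", class, call. = FALSE)
  if (length(n_px) == 1L) n_px <- c(n_px, n_px)
  structure(
    list(labels = matrix(lev, n_px[1], n_px[2]),
         pixel_size_um = pixel_size_um, classes = tissue_classes()),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat("Tissue label map:", nrow(x$labels), "x", ncol(x$labels), "px,",
      x$pixel_size_um, "um/px\n")
  tab <- table(factor(x$labels, levels = 0:3, labels = x$classes))
  print(tab)
  invisible(x)
}

#' Class mask from a label map
#' @param map A [make_label_map()] result.
#' @param class One of [tissue_classes()].
#' @return Logical H x W matrix.
#' @export
class_mask <- function(map, class) {
  lev <- match(class, map$classes) - 1L
  if (is.na(lev)) stop("unknown class: ", class, call. = FALSE)
  map$labels == lev
}

# truncated normal draws on [mean - 3 sd, mean + 3 sd] (vectorized rejection)
.rtnorm3 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(abs(x - mean) > 3 * sd)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[abs(x[bad] - mean) > 3 * sd]
  }
  x
}

#' Render a label map into a ground-truth Mueller image
#'
#' Each tissue pixel draws its depolarization from a truncated normal with
#' the class mean and standard deviation, and becomes the pure isotropic
#' depolarizer `diag(1, 1-d, 1-d, 1-d)`. In reflection geometry the
#' depolarization field is first converted to the surviving-polarization
#' convention (regions of low transmission depolarization show low surviving
#' polarization), then contrast-compressed and blurred to emulate
#' thick-tissue degradation.
#'
#' @param map A [make_label_map()] result.
#' @param model A [tissue_class_model()].
#' @param geometry `"transmission"` or `"reflection"`.
#' @param seed Integer seed for the per-pixel draws.
#' @return A [mueller_image()].
#' @export
render_mueller <- function(map, model = tissue_class_model(),
                           geometry = c("transmission", "reflection"),
                           seed = 1L) {
  geometry <- match.arg(geometry)
  set.seed(seed)
  lab <- map$labels
  present <- setdiff(map$classes[sort(unique(as.integer(lab))) + 1L],
                     "background")
  missing_cls <- setdiff(present, names(model$depol_mean))
  if (length(missing_cls))
    stop("tissue class model lacks class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  delta <- matrix(NA_real_, nrow(lab), ncol(lab))
  for (cl in present) {
    idx <- which(lab == match(cl, map$classes) - 1L)
    delta[idx] <- .rtnorm3(length(idx), model$depol_mean[[cl]],
                           model$depol_sd[[cl]])
  }
  if (geometry == "reflection") {
    tis <- !is.na(delta)
    mu <- mean(delta[tis])
    # surviving polarization tracks transmission depolarization in rank
    # order; compress contrast about the tissue mean, then blur
    surv <- model$reflection_contrast_scale * (delta - mu) + mu
    field <- delta
    field[tis] <- surv[tis]
    field[!tis] <- mu
    sig_px <- model$reflection_blur_sigma_um / map$pixel_size_um
    if (sig_px > 0) field <- EBImage::gblur(field, sigma = sig_px)
    field <- pmin(pmax(field, 0), 1)
    delta[tis] <- 1 - field[tis]   # stored as depolarization of the pixel
  }
  mueller_from_delta(delta, map$pixel_size_um, geometry)
}

#' Serial-section drift specification
#'
#' @param boundary_shift_mean_um Target mean displacement of tissue
#'   boundaries between consecutive sections, micrometres. The default
#'   (1250 um) sits at the midpoint of the 1-1.5 mm internal-border mismatch
#'   observed between serial sections about 75 um apart.
#' @param boundary_shift_sd_um Nominal spatial dispersion of the shift.
#' @param smooth_field_scale_um Correlation length of the smooth random
#'   displacement field.
#' @param seed Integer seed.
#' @return An object of class `drift_spec`.
#' @export
drift_spec <- function(boundary_shift_mean_um = 1250,
                       boundary_shift_sd_um = 125,
                       smooth_field_scale_um = 2500,
                       seed = 1L) {
  stopifnot(boundary_shift_mean_um >= 0, boundary_shift_sd_um >= 0,
            smooth_field_scale_um > 0)
  structure(
    list(boundary_shift_mean_um = boundary_shift_mean_um,
         boundary_shift_sd_um = boundary_shift_sd_um,
         smooth_field_scale_um = smooth_field_scale_um,
         seed = seed),
    class = "drift_spec"
  )
}

#' Apply serial-section morphology drift to a label map
#'
#' Warps the label map with a smooth, zero-mean random displacement field.
#' The field is scaled so that the mean displacement of region boundaries
#' along their normals equals `boundary_shift_mean_um`: for an isotropic 2-D
#' displacement the normal component averages `2/pi` of the magnitude, so the
#' field magnitude is calibrated to `pi/2` times the nominal boundary shift.
#' The spatial mean of the field is removed so that the drift cannot be
#' undone by a rigid alignment.
#'
#' @param map A [make_label_map()] result.
#' @param drift A [drift_spec()].
#' @return A drifted `label_map` with the same class set.
#' @export
serial_drift <- function(map, drift = drift_spec()) {
  if (drift$boundary_shift_mean_um == 0) return(map)
  set.seed(drift$seed)
  lab <- map$labels
  H <- nrow(lab); W <- ncol(lab)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  dxm <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  dym <- matrix(seq_len(H), H, W) - cy
  # (1) coherent internal slip along two orthogonal axes through the
  # center: each axis splits the section into halves that shift in opposite
  # directions with a smooth transition. Internal borders mismatch
  # coherently while the outer tissue border (tapered below) stays aligned,
  # and the antisymmetry makes both modes invisible to rigid-body alignment.
  phi <- stats::runif(1, 0, pi)
  band_px <- drift$smooth_field_scale_um / map$pixel_size_um
  xi1 <- tanh((cos(phi) * dxm + sin(phi) * dym) / band_px)
  phi2 <- phi + pi / 2
  xi2 <- tanh((cos(phi2) * dxm + sin(phi2) * dym) / band_px)
  sx <- -sin(phi) * xi1 - sin(phi2) * xi2
  sy <- cos(phi) * xi1 + cos(phi2) * xi2
  # (2) smooth random roughness at a quarter of the slip transition scale:
  # short enough to carry no quasi-rigid component over the tumour (which
  # alignment would simply remove), long enough to stay smooth
  sig_px <- drift$smooth_field_scale_um / map$pixel_size_um / 4
  nx <- EBImage::gblur(matrix(stats::rnorm(H * W), H, W), sigma = sig_px)
  ny <- EBImage::gblur(matrix(stats::rnorm(H * W), H, W), sigma = sig_px)
  nx <- nx - mean(nx); ny <- ny - mean(ny)
  # taper to zero toward the canvas edge: the section stays on the slide
  # while its internal morphology drifts
  rr <- sqrt(dxm^2 + dym^2)
  r_max <- min(H, W) / 2
  wgt <- ifelse(rr <= 0.60 * r_max, 1,
                ifelse(rr >= 0.80 * r_max, 0,
                       cos((rr / r_max - 0.60) / 0.20 * pi / 2)^2))
  plateau <- wgt >= 0.99
  smag <- mean(sqrt(sx^2 + sy^2)[plateau])
  nmag <- mean(sqrt(nx^2 + ny^2)[plateau])
  s_part <- list(x = sx / smag, y = sy / smag)
  n_part <- list(x = nx / nmag, y = ny / nmag)
  rough <- min(1, drift$boundary_shift_sd_um / drift$boundary_shift_mean_um)
  ux <- ((1 - rough) * s_part$x + rough * n_part$x) * wgt
  uy <- ((1 - rough) * s_part$y + rough * n_part$y) * wgt
  mag0 <- mean(sqrt(ux^2 + uy^2)[plateau])

  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  warp <- function(sx, sy) {
    si <- round(ii - sy); sj <- round(jj - sx)
    inside <- si >= 1 & si <= H & sj >= 1 & sj <= W
    out <- matrix(0L, H, W)
    out[inside] <- lab[cbind(si[inside], sj[inside])]
    fwd_i <- ii + sy; fwd_j <- jj + sx
    n_off <- sum(lab > 0L &
                   (fwd_i < 1 | fwd_i > H | fwd_j < 1 | fwd_j > W))
    list(labels = out, n_off = n_off)
  }

  # The reference mismatch is a residual after optimized rigid-body overlay,
  # and the nearest-boundary metric saturates below the raw displacement
  # when contours cross, so the field amplitude is solved for directly:
  # iterate the scale until the rigid-aligned boundary mismatch of the
  # calibration mask reaches the nominal shift, backing off whenever a trial
  # scale would push tissue off the canvas.
  cal_class <- if (any(lab == 2L)) 2L else max(lab)
  mask0 <- lab == cal_class
  target_px <- drift$boundary_shift_mean_um / map$pixel_size_um
  sc <- target_px / mag0
  sc_safe <- NA_real_
  out_safe <- NULL
  sc_unsafe <- NA_real_
  for (it in 1:14) {
    w <- warp(ux * sc, uy * sc)
    if (w$n_off > 0L) {
      sc_unsafe <- sc
      sc <- if (is.na(sc_safe)) sc / 2 else (sc + sc_safe) / 2
      next
    }
    sc_safe <- sc
    out_safe <- w$labels
    got <- boundary_mismatch(mask0, w$labels == cal_class,
                             map$pixel_size_um, align = TRUE)$mean_um /
      map$pixel_size_um
    if (abs(got - target_px) <= 0.05 * target_px) break
    sc <- sc * min(1.6, max(0.5, target_px / got))
    if (!is.na(sc_unsafe) && sc >= sc_unsafe)
      sc <- (sc_safe + sc_unsafe) / 2
  }
  if (is.null(out_safe))
    stop("drift displaces tissue off the canvas; enlarge the canvas or ",
         "reduce the shift", call. = FALSE)
  map$labels <- out_safe
  map
}
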