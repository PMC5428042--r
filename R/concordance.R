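#' TIC-normalize a DESI-MS image
#'
#' Divides every spectrum's peak intensities by its total ion current so
#' that per-spectrum intensities sum to one. Idempotent. Spectra with zero
#' TIC are replaced by `NA` intensities with a warning.
#'
#' @param img An [simulate_desi()] `ms_image` (or one read from disk).
#' @return The image with `normalized = TRUE`.
#' @export
tic_normalize <- function(img) {
  n_zero <- 0L
  img$spectra <- lapply(img$spectra, function(s) {
    tt <- sum(s$intensity)
    if (tt == 0) {
      n_zero <<- n_zero + 1L
      s$intensity <- rep(NA_real_, nrow(s))
    } else {
      s$intensity <- s$intensity / tt
    }
    s
  })
  if (n_zero > 0L)
    warning(n_zero, " zero-TIC spectra set to NA", call. = FALSE)
  img$normalized <- TRUE
  img
}

#' Extract a TIC-fraction ion image at one m/z
#'
#' Per raster pixel, sums the relative intensities of all peaks within the
#' ppm window around the query m/z (zero when no peak matches).
#'
#' @param img A TIC-normalized `ms_image`.
#' @param mz Query m/z.
#' @param tol_ppm Mass tolerance, ppm.
#' @return An object of class `ion_image`: list with `values` (H x W matrix
#'   of TIC fractions, `NA` where the spectrum was empty), `mz`, `tol_ppm`,
#'   `pixel_pitch_um` and `origin_um`.
#' @export
ion_image <- function(img, mz, tol_ppm = 20) {
  if (!isTRUE(img$normalized))
    stop("ion images are defined on TIC-normalized data; ",
         "run tic_normalize() first", call. = FALSE)
  win <- mz * tol_ppm * 1e-6
  vals <- vapply(img$spectra, function(s) {
    if (nrow(s) == 0L) return(0)
    if (anyNA(s$intensity)) return(NA_real_)
    sum(s$intensity[abs(s$mz - mz) <= win])
  }, numeric(1))
  structure(
    list(values = matrix(vals, img$dim[1], img$dim[2]), mz = mz,
         tol_ppm = tol_ppm, pixel_pitch_um = img$pixel_pitch_um,
         origin_um = img$origin_um),
    class = "ion_image"
  )
}

#' Histogram mode (center of the maximal bin)
#'
#' Bins `x` on a fixed grid starting at zero; ties between equally populated
#' bins resolve toward the lower bin.
#'
#' @param x Numeric vector (NAs dropped).
#' @param bin_width Bin width.
#' @return Center of the most populated bin.
#' @export
hist_mode <- function(x, bin_width) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  b <- floor(x / bin_width)
  tab <- table(b)
  (as.numeric(names(tab)[which.max(tab)]) + 0.5) * bin_width
}

# normalized histogram on a fixed grid
.unit_hist <- function(x, bin_width) {
  x <- x[!is.na(x)]
  brk <- seq(0, max(1, ceiling(max(x) / bin_width)) * bin_width, bin_width)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  data.frame(center = h$mids, density = h$density)
}

#' Per-ROI concordance statistics between ion images and depolarization
#'
#' For one targeted ROI, computes the mean relative abundance of each marker
#' over all MS pixels (zeros included), the fold change of the
#' hypothesis-concordant marker over the other, detected-pixel (nonzero)
#' relative-intensity histograms per marker, and the depolarization
#' histogram (percent, 2.5-point bins) with its mode and mean. Means run
#' over all pixels while histograms cover detected pixels only, reflecting
#' that a sparsely detected marker has a tight histogram but a low mean.
#'
#' @param ion_images Named list of [ion_image()]s; must contain `"viable"`
#'   (m/z 391.25) and `"necrotic"` (m/z 572.48) entries.
#' @param depol_map A [depolarization_map()] in the polarimetry frame.
#' @param roi_ A [roi()] in MS stage coordinates.
#' @param transform [rigid_transform()] mapping MS stage coordinates onto
#'   polarimetry stage coordinates (identity when the frames coincide).
#' @param intensity_bin Histogram bin width for TIC fractions.
#' @param depol_bin_pct Histogram bin width for depolarization, percent.
#' @return A list (one ConcordanceReport entry) with fields `hypothesis`,
#'   `marker_means`, `fold`, `fold_markers`, `intensity_hist` (per marker),
#'   `depol_hist`, `depol_mode_pct`, `depol_mean_pct`, `n_ms_pixels`,
#'   `n_depol_pixels`.
#' @export
roi_stats <- function(ion_images, depol_map, roi_,
                      transform = rigid_transform(),
                      intensity_bin = 0.025, depol_bin_pct = 2.5) {
  ref <- ion_images[[1L]]
  H <- nrow(ref$values); W <- ncol(ref$values)
  xs <- ref$origin_um[1] + (seq_len(W) - 0.5) * ref$pixel_pitch_um
  ys <- ref$origin_um[2] + (seq_len(H) - 0.5) * ref$pixel_pitch_um
  in_x <- abs(xs - roi_$center_um[1]) <= roi_$width_um / 2
  in_y <- abs(ys - roi_$center_um[2]) <= roi_$height_um / 2
  if (!any(in_x) || !any(in_y))
    stop("ROI lies outside the MS image frame", call. = FALSE)

  marker_vals <- lapply(ion_images, function(im) im$values[in_y, in_x])
  marker_means <- vapply(marker_vals, function(v) mean(v, na.rm = TRUE),
                         numeric(1))
  dominant <- if (roi_$hypothesis == "viable") "viable" else "necrotic"
  other <- setdiff(c("viable", "necrotic"), dominant)
  fold <- marker_means[[dominant]] / marker_means[[other]]
  ih <- lapply(marker_vals, function(v) {
    nz <- v[!is.na(v) & v > 0]
    if (length(nz)) .unit_hist(nz, intensity_bin) else NULL
  })

  # depolarization pixels of the ROI, via the stage -> polarimetry transform
  pxp <- depol_map$pixel_size_um
  Hp <- nrow(depol_map$values); Wp <- ncol(depol_map$values)
  corners <- rbind(
    roi_$center_um + c(-1, -1) * c(roi_$width_um, roi_$height_um) / 2,
    roi_$center_um + c(1, 1) * c(roi_$width_um, roi_$height_um) / 2)
  pc <- apply_transform(transform, corners)
  j1 <- max(1L, floor(min(pc[, 1]) / pxp) + 1L)
  j2 <- min(Wp, ceiling(max(pc[, 1]) / pxp))
  i1 <- max(1L, floor(min(pc[, 2]) / pxp) + 1L)
  i2 <- min(Hp, ceiling(max(pc[, 2]) / pxp))
  if (j1 > j2 || i1 > i2)
    stop("ROI lies outside the polarimetry frame", call. = FALSE)
  dvals <- depol_map$values[i1:i2, j1:j2]
  dpct <- 100 * dvals[!is.na(dvals)]

  list(hypothesis = roi_$hypothesis,
       marker_means = marker_means,
       fold = unname(fold),
       fold_markers = paste(dominant, "/", other),
       intensity_hist = ih,
       depol_hist = if (length(dpct)) .unit_hist(dpct, depol_bin_pct) else NULL,
       depol_mode_pct = hist_mode(dpct, depol_bin_pct),
       depol_mean_pct = mean(dpct),
       n_ms_pixels = sum(in_y) * sum(in_x),
       n_depol_pixels = length(dpct))
}

#' Summarize polarimetry-MS concordance over a set of ROIs
#'
#' Compares each ROI's polarimetric class (from its depolarization level
#' against the supplied thresholds) with the dominant MS marker and flags
#' the ROI concordant or discordant. Border ROIs are judged by their
#' depolarization mean falling between the thresholds and their marker
#' means being within `border_ratio` of each other.
#'
#' @param entries List of [roi_stats()] results.
#' @param lower_pct,upper_pct Depolarization thresholds (percent) separating
#'   viable / border / necrotic calls.
#' @param border_ratio Maximal marker-mean fold still considered "mixed" for
#'   border ROIs.
#' @return An object of class `concordance_summary`: data frame with one row
#'   per ROI (`hypothesis`, `depol_mean_pct`, `depol_class`,
#'   `dominant_marker`, `fold`, `verdict`) plus attribute
#'   `fraction_concordant`.
#' @export
concordance_summary <- function(entries, lower_pct = 25, upper_pct = 30,
                                border_ratio = 2) {
  if (!length(entries)) {
    out <- data.frame(hypothesis = character(0),
                      depol_mean_pct = numeric(0),
                      depol_class = character(0),
                      dominant_marker = character(0),
                      fold = numeric(0), verdict = character(0))
    attr(out, "fraction_concordant") <- NA_real_
    class(out) <- c("concordance_summary", "data.frame")
    return(out)
  }
  rows <- lapply(entries, function(e) {
    depol_class <- if (e$depol_mean_pct >= upper_pct) "necrotic"
      else if (e$depol_mean_pct <= lower_pct) "viable" else "border"
    mm <- e$marker_means[c("viable", "necrotic")]
    ratio <- max(mm) / min(mm)
    dominant <- if (ratio <= border_ratio) "mixed"
      else names(mm)[which.max(mm)]
    concordant <- (depol_class == "border" && dominant == "mixed") ||
      (depol_class == dominant)
    data.frame(hypothesis = e$hypothesis,
               depol_mean_pct = e$depol_mean_pct,
               depol_class = depol_class,
               dominant_marker = dominant,
               fold = e$fold,
               verdict = if (concordant) "concordant" else "discordant")
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_concordant") <- mean(out$verdict == "concordant")
  class(out) <- c("concordance_summary", "data.frame")
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Polarimetry-MS concordance:", nrow(x), "ROIs")
  if (nrow(x))
    cat(sprintf(", %.0f%% concordant",
                100 * attr(x, "fraction_concordant")))
  cat("\n")
  if (nrow(x)) print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
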