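#' Default marker-ion profiles per tissue class
#'
#' Lipid marker chemistry of the breast-tumour model, expressed as per-class
#' detection probabilities and relative-intensity (TIC fraction) Beta
#' distributions parameterized by mode and concentration. The viable-cancer
#' marker is m/z 391.25 and the necrotic-cancer marker m/z 572.48
#' ([Cer(d34:1)+Cl]-); m/z 303.23 (arachidonic acid) is present in both
#' cancer classes and rarer in muscle; 281.25 (oleic acid) and 331.26
#' (adrenic acid) are generic breast-tissue lipids. In the dominant class the
#' marker distribution is wide (low concentration); in the opposite class it
#' is tight and less populous, so that detected-pixel histogram modes
#' (0.45 / 0.35 dominant, 0.15 / 0.13 recessive) and all-pixel mean fold
#' changes (5-6 and 3-4) hold simultaneously.
#'
#' @return Named list (one element per tissue class) of data frames with
#'   columns `mz`, `presence_prob`, `intensity_mode`, `concentration`.
#' @export
default_marker_profiles <- function() {
  list(
    necrotic = data.frame(
      mz             = c(572.48, 391.25, 303.23, 281.25, 331.26),
      presence_prob  = c(0.95,   0.55,   0.80,   0.80,   0.60),
      intensity_mode = c(0.45,   0.15,   0.05,   0.05,   0.03),
      concentration  = c(30,     200,    150,    150,    200)
    ),
    viable = data.frame(
      mz             = c(391.25, 572.48, 303.23, 281.25, 331.26),
      presence_prob  = c(0.95,   0.70,   0.85,   0.80,   0.60),
      intensity_mode = c(0.35,   0.13,   0.06,   0.05,   0.03),
      concentration  = c(100,    200,    150,    150,    200)
    ),
    muscle = data.frame(
      mz             = c(303.23, 281.25, 255.23),
      presence_prob  = c(0.30,   0.70,   0.80),
      intensity_mode = c(0.03,   0.05,   0.06),
      concentration  = c(200,    150,    150)
    ),
    background = data.frame(
      mz             = numeric(0),
      presence_prob  = numeric(0),
      intensity_mode = numeric(0),
      concentration  = numeric(0)
    )
  )
}

#' Construct a centroided spectrum
#'
#' @param mz Numeric vector of m/z values (Thomson).
#' @param intensity Non-negative numeric vector of peak intensities.
#' @param coords_um Optional stage coordinates `c(x, y)` in micrometres.
#' @param acquisition_s Acquisition duration in seconds.
#' @return A data frame of class `spectrum` with columns `mz` (strictly
#'   increasing) and `intensity`.
#' @export
spectrum <- function(mz, intensity, coords_um = NULL, acquisition_s = 1) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0),
            all(mz > 0))
  o <- order(mz)
  s <- data.frame(mz = mz[o], intensity = intensity[o])
  if (anyDuplicated(s$mz)) {
    s <- stats::aggregate(intensity ~ mz, s, sum)
    s <- s[order(s$mz), c("mz", "intensity")]
  }
  structure(s, class = c("spectrum", "data.frame"),
            coords_um = coords_um, acquisition_s = acquisition_s)
}

#' Total ion current of a spectrum
#' @param s A [spectrum()].
#' @return Sum of peak intensities.
#' @export
tic <- function(s) sum(s$intensity)

# Beta draw parameterized by mode and concentration (alpha + beta = conc)
.rbeta_mode <- function(n, mode, conc) {
  stats::rbeta(n, mode * (conc - 2) + 1, (1 - mode) * (conc - 2) + 1)
}

# random background m/z keeping clear of the marker windows
.background_mz <- function(n, avoid_mz, mz_range = c(200, 1000),
                           clear_ppm = 200) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(n, mz_range[1], mz_range[2])
    if (length(avoid_mz)) {
      ok <- vapply(cand, function(m)
        all(abs(m - avoid_mz) / avoid_mz > clear_ppm * 1e-6), logical(1))
      cand <- cand[ok]
    }
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# one simulated spectrum for a tissue class
.simulate_spectrum <- function(profile, coords_um = NULL, acquisition_s = 1,
                               mz_jitter_ppm = 5, n_background = 30,
                               tic_mean = 1e4) {
  total <- stats::rlnorm(1, log(tic_mean * acquisition_s), 0.2)
  frac <- numeric(0); mzv <- numeric(0)
  if (nrow(profile)) {
    det <- stats::runif(nrow(profile)) < profile$presence_prob
    if (any(det)) {
      frac <- .rbeta_mode(sum(det), profile$intensity_mode[det],
                          profile$concentration[det])
      mzv <- profile$mz[det] *
        (1 + stats::rnorm(sum(det), 0, mz_jitter_ppm * 1e-6))
    }
  }
  s <- sum(frac)
  if (s > 1) { frac <- frac / s; s <- 1 }   # cap: fractions sum <= 1
  bg_w <- stats::rgamma(n_background, 1.5)
  bg_frac <- (1 - s) * bg_w / sum(bg_w)
  bg_mz <- .background_mz(n_background, profile$mz)
  spectrum(c(mzv, bg_mz), c(frac, bg_frac) * total,
           coords_um = coords_um, acquisition_s = acquisition_s)
}

#' Simulate a DESI-MS raster image over a label map
#'
#' Rasters a region of the label map at the stage pitch (default 100 um,
#' matching a 100 um/s stage and 1 s spectral integration). Each raster
#' pixel takes the majority tissue class within its footprint, detects each
#' of that class's marker ions with its presence probability, draws detected
#' relative intensities from the class Beta law, and fills the remaining
#' total ion current with an unstructured background ion population.
#'
#' @param map A [make_label_map()] result.
#' @param profiles Marker profiles as from [default_marker_profiles()].
#' @param roi Optional [roi()] restricting the raster; `NULL` rasters the
#'   whole map.
#' @param pixel_pitch_um Raster pitch in micrometres.
#' @param integration_s Spectral integration time per pixel, seconds.
#' @param stage_speed_um_s Stage speed, micrometres per second.
#' @param seed Integer seed; the raster is deterministic given the seed.
#' @return An object of class `ms_image`: list with `spectra` (list, column-
#'   major over the raster grid), `dim` `c(ny, nx)`, `pixel_pitch_um`,
#'   `origin_um` (stage coordinates of the grid corner), `raster` parameters
#'   and `normalized` flag.
#' @export
simulate_desi <- function(map, profiles = default_marker_profiles(),
                          roi = NULL, pixel_pitch_um = 100,
                          integration_s = 1, stage_speed_um_s = 100,
                          seed = 1L) {
  set.seed(seed)
  px <- map$pixel_size_um
  H <- nrow(map$labels); W <- ncol(map$labels)
  if (is.null(roi)) {
    x0 <- 0; y0 <- 0
    w_um <- W * px; h_um <- H * px
  } else {
    x0 <- roi$center_um[1] - roi$width_um / 2
    y0 <- roi$center_um[2] - roi$height_um / 2
    w_um <- roi$width_um; h_um <- roi$height_um
  }
  nx <- max(1L, floor(w_um / pixel_pitch_um))
  ny <- max(1L, floor(h_um / pixel_pitch_um))
  if (nx * ny == 0L) stop("empty ROI", call. = FALSE)
  missing_cls <- setdiff(
    tissue_classes()[sort(unique(as.integer(map$labels))) + 1L],
    names(profiles))
  if (length(missing_cls))
    stop("marker profiles lack class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  spectra <- vector("list", nx * ny)
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      cx_um <- x0 + (ix - 0.5) * pixel_pitch_um
      cy_um <- y0 + (iy - 0.5) * pixel_pitch_um
      j1 <- max(1L, floor((cx_um - pixel_pitch_um / 2) / px) + 1L)
      j2 <- min(W, ceiling((cx_um + pixel_pitch_um / 2) / px))
      i1 <- max(1L, floor((cy_um - pixel_pitch_um / 2) / px) + 1L)
      i2 <- min(H, ceiling((cy_um + pixel_pitch_um / 2) / px))
      if (j1 > j2 || i1 > i2) stop("ROI outside map bounds", call. = FALSE)
      block <- map$labels[i1:i2, j1:j2]
      maj <- as.integer(names(which.max(table(block))))
      cls <- tissue_classes()[maj + 1L]
      spectra[[(ix - 1L) * ny + iy]] <-
        .simulate_spectrum(profiles[[cls]], coords_um = c(cx_um, cy_um),
                           acquisition_s = integration_s)
    }
  }
  structure(
    list(spectra = spectra, dim = c(ny, nx), pixel_pitch_um = pixel_pitch_um,
         origin_um = c(x0, y0),
         raster = list(stage_speed_um_s = stage_speed_um_s,
                       integration_s = integration_s),
         normalized = FALSE),
    class = "ms_image"
  )
}

#' @export
print.ms_image <- function(x, ...) {
  cat("DESI-MS image:", x$dim[1], "x", x$dim[2], "pixels at",
      x$pixel_pitch_um, "um pitch",
      if (x$normalized) "(TIC-normalized)" else "", "\n")
  invisible(x)
}

#' Mouse-organ PIRL-MS peak panel
#'
#' All organs share a panel of fatty-acid and phospholipid peaks whose
#' relative intensities form an organ-characteristic pattern; each organ
#' additionally carries one or two organ-unique m/z values. Tissue identity
#' is thus encoded mostly quantitatively (as in real lipid profiles), with
#' presence/absence markers on top.
#'
#' @return Named list per organ of data frames `mz`, `rate` (expected counts
#'   per second of sampling).
#' @export
organ_panel <- function() {
  fa <- c(255.23, 281.25, 303.23, 331.26)
  fa_rate <- c(600, 900, 700, 400)
  pl <- c(687.54, 699.50, 716.52, 734.57, 747.52, 760.51,
          766.54, 788.54, 810.53, 834.53, 863.56, 885.55)
  base <- c(1000, 780, 620, 480, 380, 300, 240, 190, 150, 120, 95, 75)
  uniq <- list(liver  = c(865.50, 891.58),
               kidney = c(806.49, 822.51),
               brain  = c(888.62, 834.60),
               lung   = c(723.49, 771.52),
               heart  = c(748.53, 852.55),
               spleen = c(782.50, 835.53))
  out <- list()
  for (k in seq_along(uniq)) {
    # rotate the phospholipid intensity pattern per organ
    rot <- ((seq_along(pl) - 1L + 3L * (k - 1L)) %% length(pl)) + 1L
    out[[names(uniq)[k]]] <- data.frame(
      mz = c(fa, pl, uniq[[k]]),
      rate = c(fa_rate, base[rot], c(500, 350)))
  }
  out
}

# breast tissue-class PIRL profiles: breast lipids + class markers
.pirl_breast_panel <- function() {
  breast <- data.frame(mz = c(281.25, 303.23, 331.26),
                       rate = c(900, 800, 500))
  list(
    viable = rbind(breast, data.frame(mz = 391.25, rate = 1200)),
    necrotic = rbind(breast,
                     data.frame(mz = c(572.48, 391.25), rate = c(1200, 150)))
  )
}

#' Simulate a PIRL point-sampling spectrum
#'
#' Peak counts are Poisson with expectation `rate * duration_s`, so expected
#' intensities scale linearly with sampling time; 5-10 s of sampling gives
#' well-populated spectra. Breast tissue classes (`"viable"`, `"necrotic"`)
#' carry the breast lipid ions 281.25 / 303.23 / 331.26 plus the class
#' markers 391.25 / 572.48; mouse organs come from [organ_panel()].
#'
#' @param class_or_organ A tissue class (`"viable"`, `"necrotic"`) or an
#'   organ name from [organ_panel()].
#' @param duration_s Sampling duration in seconds (> 0).
#' @param seed Integer seed.
#' @param mz_jitter_ppm Gaussian m/z jitter, ppm.
#' @return A [spectrum()].
#' @export
simulate_pirl <- function(class_or_organ, duration_s = 10, seed = 1L,
                          mz_jitter_ppm = 5) {
  if (duration_s <= 0)
    stop("duration_s must be > 0: a zero-duration sample has no spectrum",
         call. = FALSE)
  panel <- c(.pirl_breast_panel(), organ_panel())
  if (!class_or_organ %in% names(panel))
    stop("unknown tissue class or organ '", class_or_organ,
         "'; available: ", paste(names(panel), collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  p <- panel[[class_or_organ]]
  counts <- stats::rpois(nrow(p), p$rate * duration_s)
  mz <- p$mz * (1 + stats::rnorm(nrow(p), 0, mz_jitter_ppm * 1e-6))
  keep <- counts > 0
  spectrum(mz[keep], counts[keep], acquisition_s = duration_s)
}

#' Match a query m/z against a spectrum within a ppm tolerance
#'
#' Returns the nearest peak whose relative mass deviation is within
#' `tol_ppm`; ties in distance are broken toward the more intense peak.
#'
#' @param s A [spectrum()].
#' @param query_mz Query m/z.
#' @param tol_ppm Mass tolerance, parts per million.
#' @return A list `(mz, intensity, ppm)` or `NULL` when no peak matches.
#' @examples
#' s <- spectrum(c(391.253, 500), c(10, 5))
#' match_mz(s, 391.25, 20)$ppm  # ~7.7 ppm
#' @export
match_mz <- function(s, query_mz, tol_ppm = 20) {
  stopifnot(tol_ppm > 0)
  if (nrow(s) == 0L) return(NULL)
  ppm <- abs(s$mz - query_mz) / query_mz * 1e6
  ok <- which(ppm <= tol_ppm)
  if (!length(ok)) return(NULL)
  best <- ok[order(ppm[ok], -s$intensity[ok])][1L]
  list(mz = s$mz[best], intensity = s$intensity[best], ppm = ppm[best])
}
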