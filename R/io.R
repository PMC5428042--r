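#' Write a polarization stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are written in instrument pair order as 32-bit float pages;
#' generator/analyzer states and pairing go to `<path>.json`.
#'
#' @param stack A [simulate_stack()] result.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  sc <- max(stack$frames)
  pages <- lapply(seq_len(nrow(stack$frames)), function(k)
    matrix(stack$frames[k, ] / sc, stack$dim[1], stack$dim[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  inst <- stack$instrument
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um, geometry = stack$geometry,
         intensity_scale = sc,
         psg_states = t(inst$psg), psa_states = t(inst$psa),
         pairs = inst$pairs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polarization stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @param instrument The [build_instrument()] model used at acquisition.
#' @return A `polarization_stack`.
#' @export
read_stack_tiff <- function(path, instrument) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- do.call(rbind, lapply(pages, as.numeric)) * meta$intensity_scale
  structure(
    list(frames = frames, dim = dim(pages[[1]]), instrument = instrument,
         pixel_size_um = meta$pixel_size_um, geometry = meta$geometry,
         n_clamped = 0L),
    class = "polarization_stack"
  )
}

#' Write a depolarization map as float TIFF and grayscale PNG
#'
#' @param map A [depolarization_map()].
#' @param path Base output path; `.tif` and `.png` extensions are appended.
#' @return Invisibly, the two file paths.
#' @export
write_depol_map <- function(map, path) {
  v <- map$values
  v[is.na(v)] <- 0
  tif <- paste0(path, ".tif"); pngf <- paste0(path, ".png")
  tiff::writeTIFF(pmin(pmax(v, 0), 1), tif, bits.per.sample = 32L)
  png::writePNG(pmin(pmax(v, 0), 1), pngf)
  invisible(c(tif, pngf))
}

#' Write / read a label map as PNG plus JSON class table
#'
#' @param map A [make_label_map()] result.
#' @param path Base path; `.png` and `.json` are appended.
#' @return Invisibly, `path`.
#' @export
write_label_map <- function(map, path) {
  png::writePNG(map$labels / max(1L, length(map$classes) - 1L),
                paste0(path, ".png"))
  jsonlite::write_json(
    list(classes = map$classes, pixel_size_um = map$pixel_size_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  img <- png::readPNG(paste0(path, ".png"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(labels = matrix(as.integer(round(img * (length(meta$classes) - 1L))),
                         nrow(img), ncol(img)),
         pixel_size_um = meta$pixel_size_um, classes = meta$classes),
    class = "label_map"
  )
}

#' Write an MS image as a long-format CSV
#'
#' Columns `x_um`, `y_um`, `mz`, `intensity`; one row per peak.
#'
#' @param img An `ms_image`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ms_csv <- function(img, path) {
  rows <- lapply(img$spectra, function(s) {
    co <- attr(s, "coords_um")
    if (nrow(s) == 0L) return(NULL)
    data.frame(x_um = co[1], y_um = co[2], mz = s$mz,
               intensity = s$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an MS image from long-format CSV
#'
#' @param path CSV path as written by [write_ms_csv()].
#' @param pixel_pitch_um Raster pitch of the stored grid.
#' @param normalized Whether the stored intensities are TIC fractions.
#' @return An `ms_image`.
#' @export
read_ms_csv <- function(path, pixel_pitch_um = 100, normalized = FALSE) {
  d <- utils::read.csv(path)
  xs <- sort(unique(d$x_um)); ys <- sort(unique(d$y_um))
  origin <- c(min(xs) - pixel_pitch_um / 2, min(ys) - pixel_pitch_um / 2)
  spectra <- vector("list", length(xs) * length(ys))
  for (ix in seq_along(xs)) for (iy in seq_along(ys)) {
    sel <- d$x_um == xs[ix] & d$y_um == ys[iy]
    spectra[[(ix - 1L) * length(ys) + iy]] <-
      spectrum(d$mz[sel], d$intensity[sel], coords_um = c(xs[ix], ys[iy]))
  }
  structure(
    list(spectra = spectra, dim = c(length(ys), length(xs)),
         pixel_pitch_um = pixel_pitch_um, origin_um = origin,
         raster = list(stage_speed_um_s = 100, integration_s = 1),
         normalized = normalized),
    class = "ms_image"
  )
}

#' Write a spectrum as a two-column CSV
#' @param s A [spectrum()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(data.frame(mz = s$mz, intensity = s$intensity), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  spectrum(d$mz, d$intensity)
}

#' Write ROI lists and rigid transforms to JSON
#' @param rois List of [roi()] objects.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_rois_json <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
         function(r) roi(unlist(r$center_um), r$width_um, r$height_um,
                         r$hypothesis))
}
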