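#' Default configuration for an end-to-end guided-workflow run
#'
#' A run is reproducible from its configuration alone: every stochastic
#' stage derives its seed from `seed`. The default phantom is a 1.7 cm x
#' 1.7 cm slice at 17 um/px; for ROI guidance the polarimetric round trip is
#' run at a binned resolution (`polarimetry$binning`, default 4, i.e.
#' 68 um/px) which preserves millimetre-scale depolarization contrast while
#' keeping the per-pixel decomposition cheap.
#'
#' @param seed Master seed.
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged shallowly per section).
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    phantom = list(n_px = c(1000L, 1000L), pixel_size_um = 17,
                   tissue_frac = 0.36, tumour_frac = 0.30,
                   necrotic_frac = 0.12, wobble = 0.04),
    polarimetry = list(noise = "gaussian", noise_sd = 0.01, binning = 4L,
                       geometry = "transmission"),
    rois = list(n_necrotic = 3L, n_viable = 3L, n_border = 2L,
                margin = 0.05),
    raster = list(pixel_pitch_um = 100, integration_s = 1,
                  stage_speed_um_s = 100),
    concordance = list(lower_pct = 25, upper_pct = 30, border_ratio = 2,
                       viable_mz = 391.25, necrotic_mz = 572.48,
                       tol_ppm = 20)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly, or the parsed `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = cfg$seed),
                        cfg[setdiff(names(cfg), "seed")]))
}

#' Stable hash of a run configuration
#' @param cfg A [run_config()].
#' @return Character MD5 digest of the canonical JSON form.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

# coarsen a label map by integer subsampling (nearest pixel)
.bin_label_map <- function(map, factor) {
  if (factor <= 1L) return(map)
  H <- nrow(map$labels); W <- ncol(map$labels)
  ii <- seq(ceiling(factor / 2), H, by = factor)
  jj <- seq(ceiling(factor / 2), W, by = factor)
  map$labels <- map$labels[ii, jj]
  map$pixel_size_um <- map$pixel_size_um * factor
  map
}

#' Run the full polarimetry-guided DESI-MS workflow
#'
#' Executes phantom generation, polarimetric acquisition (24-frame forward
#' simulation with noise), Mueller reconstruction, Lu-Chipman depolarization
#' mapping, ROI proposal, targeted DESI-MS simulation of each ROI, TIC
#' normalization, ion-image extraction and per-ROI concordance statistics.
#' When `out_dir` is given, the stages write their artifacts (config YAML,
#' label map, depolarization map, ROI list, concordance report JSON) plus a
#' run manifest with the config hash and wall time.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory.
#' @return List with elements `label_map`, `depol_map`, `rois`, `plan`,
#'   `speedup`, `entries` (per-ROI [roi_stats()]), and `summary`
#'   ([concordance_summary()]).
#' @export
run_workflow <- function(cfg = run_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  ph <- cfg$phantom
  map <- make_label_map(n_px = ph$n_px, pixel_size_um = ph$pixel_size_um,
                        tissue_frac = ph$tissue_frac,
                        tumour_frac = ph$tumour_frac,
                        necrotic_frac = ph$necrotic_frac,
                        wobble = ph$wobble, seed = cfg$seed)

  pol <- cfg$polarimetry
  map_pol <- .bin_label_map(map, pol$binning)
  truth <- render_mueller(map_pol, geometry = pol$geometry,
                          seed = cfg$seed + 1L)
  inst <- build_instrument()
  stack <- simulate_stack(truth, inst, noise = pol$noise,
                          noise_sd = pol$noise_sd, seed = cfg$seed + 2L)
  recon <- reconstruct_mueller(stack)
  dmap <- depolarization_map(recon)

  rq <- cfg$rois
  rois <- propose_rois(dmap, n_necrotic = rq$n_necrotic,
                       n_viable = rq$n_viable, n_border = rq$n_border,
                       margin = rq$margin)
  plan <- scan_plan(rois, pixel_pitch_um = cfg$raster$pixel_pitch_um,
                    integration_s = cfg$raster$integration_s,
                    stage_speed_um_s = cfg$raster$stage_speed_um_s)
  fov_um <- rev(ph$n_px) * ph$pixel_size_um
  fold <- speedup(fov_um, plan)

  cc <- cfg$concordance
  entries <- lapply(seq_along(rois), function(k) {
    ms <- simulate_desi(map, roi = rois[[k]],
                        pixel_pitch_um = cfg$raster$pixel_pitch_um,
                        integration_s = cfg$raster$integration_s,
                        seed = cfg$seed + 10L + k)
    ms <- tic_normalize(ms)
    imgs <- list(viable = ion_image(ms, cc$viable_mz, cc$tol_ppm),
                 necrotic = ion_image(ms, cc$necrotic_mz, cc$tol_ppm))
    roi_stats(imgs, dmap, rois[[k]])
  })
  summary <- concordance_summary(entries, lower_pct = cc$lower_pct,
                                 upper_pct = cc$upper_pct,
                                 border_ratio = cc$border_ratio)
  res <- list(label_map = map, depol_map = dmap, rois = rois, plan = plan,
              speedup = fold, entries = entries, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(cfg, file.path(out_dir, "config.yaml"))
    write_label_map(map, file.path(out_dir, "label_map"))
    write_depol_map(dmap, file.path(out_dir, "depolarization"))
    write_rois_json(rois, file.path(out_dir, "rois.json"))
    jsonlite::write_json(
      list(rois = lapply(entries, function(e)
        list(hypothesis = e$hypothesis,
             marker_means = as.list(e$marker_means),
             fold = e$fold,
             depol_mode_pct = e$depol_mode_pct,
             depol_mean_pct = e$depol_mean_pct)),
        speedup = fold,
        scan_time_s = scan_time(plan),
        fraction_concordant = attr(summary, "fraction_concordant")),
      file.path(out_dir, "concordance.json"),
      auto_unbox = TRUE, digits = 10)
    jsonlite::write_json(
      list(config_hash = config_hash(cfg), seed = cfg$seed,
           wall_time_s = round(proc.time()[["elapsed"]] - t0, 2),
           stages = c("phantom", "acquire", "reconstruct", "guide",
                      "desi", "analyze")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
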