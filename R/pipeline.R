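#' Pipeline configuration
#'
#' Bundles every stage's parameters into one validated object that
#' round-trips losslessly through JSON.  Unknown keys are rejected so stale
#' or misspelled configuration cannot silently change a run.  Geometry keys
#' mirror the scan-table column names (`l_nm`, `n_projections`, `exposure_s`,
#' `photons_per_pixel_projection`, `d1_mm`).
#'
#' @param phantom list of [phantom_spec()]-style keys (`shape`, `spacing`,
#'   `n_cells`, `radius_range`, `noise_sigma`, `psf_sigma`,
#'   `neuropil_density`, `neuropil_texture_sigma`,
#'   `neuropil_texture_amplitude`, `prescan_bin`, `roi_shape`).
#' @param geometry list of scan-table keys (see above, plus
#'   `photon_energy_kev`, `detector_pixel_um`, `focus_detector_distance_mm`).
#' @param frangi,sfm lists overriding [frangi_params()] / [sfm_params()]
#'   defaults.
#' @param metrics list: `min_overlap`, `median_slices`.
#' @param out_dir run directory.
#' @param seed global seed, from which all stage seeds derive.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `PipelineConfig` object.
#' @export
pipeline_config <- function(phantom = list(), geometry = list(),
                            frangi = list(), sfm = list(), metrics = list(),
                            out_dir = "nanoholo-run", seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  defaults <- list(
    phantom = list(shape = c(160, 160, 160), spacing = 200, n_cells = 6,
                   radius_range = c(15, 25), noise_sigma = 0.05,
                   psf_sigma = 1, neuropil_density = 0.45,
                   neuropil_texture_sigma = 3,
                   neuropil_texture_amplitude = 0.02,
                   prescan_bin = 4L, roi_shape = c(128, 128, 128)),
    geometry = list(sample = "cerebellum", l_nm = 25, n_projections = 1800,
                    exposure_s = 0.25, photons_per_pixel_projection = 500,
                    d1_mm = c(10.066, 10.499, 12.226, 15.812),
                    photon_energy_kev = 17, detector_pixel_um = 3,
                    focus_detector_distance_mm = 1208),
    frangi = formals_defaults(frangi_params),
    sfm = formals_defaults(sfm_params),
    metrics = list(min_overlap = 0.5, median_slices = 10))
  sections <- list(phantom = phantom, geometry = geometry, frangi = frangi,
                   sfm = sfm, metrics = metrics)
  merged <- lapply(names(sections), function(nm) {
    given <- sections[[nm]]
    allowed <- names(defaults[[nm]])
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("parameter error: unknown ", nm, " key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    utils::modifyList(defaults[[nm]], given)
  })
  names(merged) <- names(sections)
  structure(c(merged, list(out_dir = out_dir, seed = as.integer(seed),
                           log_level = log_level)),
            class = "PipelineConfig")
}

formals_defaults <- function(fn) {
  out <- lapply(formals(fn), function(v)
    tryCatch(eval(v), error = function(e) NULL))
  out[!vapply(out, is.null, TRUE)]
}

#' @rdname pipeline_config
#' @param config a `PipelineConfig`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("phantom", "geometry", "frangi", "sfm", "metrics",
             "out_dir", "seed", "log_level")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("parameter error: unknown config key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  pipeline_config(phantom = as.list(raw$phantom),
                  geometry = as.list(raw$geometry),
                  frangi = as.list(raw$frangi), sfm = as.list(raw$sfm),
                  metrics = as.list(raw$metrics),
                  out_dir = raw$out_dir, seed = raw$seed,
                  log_level = raw$log_level)
}

config_checksum <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

plog <- function(config, ...) {
  if (identical(config$log_level, "info"))
    message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  invisible(NULL)
}

config_phantom_spec <- function(config, shape, seed,
                                radius_sampler = NULL) {
  ph <- config$phantom
  cells <- with_seed(seed + 1000L, lapply(seq_len(ph$n_cells), function(i)
    cell_spec(center = NULL,
              radii = stats::runif(3, ph$radius_range[1],
                                   ph$radius_range[2]))))
  phantom_spec(shape = shape, spacing = ph$spacing,
               neuropil_density = ph$neuropil_density,
               neuropil_texture_sigma = ph$neuropil_texture_sigma,
               neuropil_texture_amplitude = ph$neuropil_texture_amplitude,
               cells = cells, psf_sigma = ph$psf_sigma,
               noise_sigma = ph$noise_sigma, rng_seed = seed)
}

config_frangi <- function(config) do.call(frangi_params, config$frangi)
config_sfm <- function(config) do.call(sfm_params, config$sfm)

# densest-cell ROI: window of `roi_shape` maximizing detection response mass
select_roi <- function(response, roi_shape) {
  arr <- response$voxels
  d <- dim(arr)
  roi_shape <- pmin(roi_shape, d)
  cs <- apply(arr, c(2, 3), cumsum)            # cumsum along z
  cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3)) # along y
  cs <- aperm(apply(cs, c(1, 2), cumsum), c(2, 3, 1)) # along x
  # box sum via inclusion-exclusion on the 3-D cumulative sum
  pad <- array(0, d + 1)
  pad[-1, -1, -1] <- cs
  lo <- lapply(1:3, function(ax) seq_len(d[ax] - roi_shape[ax] + 1L))
  best <- NULL; best_val <- -Inf
  for (z in lo[[1]]) for (y in lo[[2]]) for (x in lo[[3]]) {
    z2 <- z + roi_shape[1]; y2 <- y + roi_shape[2]; x2 <- x + roi_shape[3]
    s <- pad[z2, y2, x2] - pad[z, y2, x2] - pad[z2, y, x2] - pad[z2, y2, x] +
      pad[z, y, x2] + pad[z, y2, x] + pad[z2, y, x] - pad[z, y, x]
    if (s > best_val) { best_val <- s; best <- c(z, y, x) }
  }
  list(start = best, shape = roi_shape, mass = best_val)
}

#' Run the hierarchical imaging-and-analysis pipeline
#'
#' Emulates the instrument's multi-resolution workflow at desk scale:
#' generate the master phantom, bin it to a fast overview prescan, select
#' the region of interest with the highest detection-response mass (the
#' deterministic stand-in for the expert's choice), segment the
#' full-resolution region with the two-step automated framework, and
#' evaluate sensitivity and contrast metrics against the ground truth.  All
#' artifacts, a metrics report and a provenance manifest (config checksum,
#' seed, versions, photon budget) are written to `config$out_dir`; rerunning
#' the same config reproduces the report.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the run directory; the `report` and `manifest` are
#'   attached as attributes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- config$phantom
  plog(config, "phantom: master volume %s", paste(ph$shape, collapse = "x"))
  spec <- config_phantom_spec(config, ph$shape, config$seed)
  master <- generate_tissue_phantom(spec)

  plog(config, "prescan: binning by %d", ph$prescan_bin)
  prescan <- bin_volume(master$intensity, ph$prescan_bin)
  fp <- config_frangi(config)
  fp_coarse <- fp
  fp_coarse$radius_min <- max(2, fp$radius_min / ph$prescan_bin)
  fp_coarse$radius_max <- max(3, fp$radius_max / ph$prescan_bin)
  fp_coarse$radius_step <- max(1, fp$radius_step / ph$prescan_bin)
  fp_coarse$min_object_voxels <- max(
    1, fp$min_object_voxels %/% ph$prescan_bin^3)
  resp_coarse <- frangi_response(prescan, fp_coarse)
  roi_coarse <- select_roi(resp_coarse,
                           pmax(1L, ph$roi_shape %/% ph$prescan_bin))
  start <- (roi_coarse$start - 1L) * ph$prescan_bin + 1L
  shape <- pmin(ph$roi_shape, ph$shape - start + 1L)
  plog(config, "ROI at (%s), shape (%s)", paste(start - 1L, collapse = ","),
       paste(shape, collapse = ","))
  rz <- start[1]:(start[1] + shape[1] - 1L)
  ry <- start[2]:(start[2] + shape[2] - 1L)
  rx <- start[3]:(start[3] + shape[3] - 1L)
  roi_v <- volume3d(master$intensity$voxels[rz, ry, rx, drop = FALSE],
                    spec$spacing)
  roi_lab <- volume3d(master$labels$voxels[rz, ry, rx, drop = FALSE],
                      spec$spacing)

  plog(config, "segmentation: two-step automated framework")
  sp <- config_sfm(config)
  seg <- segment_automated(roi_v, fp, sp)

  plog(config, "metrics")
  sens <- sensitivity(seg, roi_lab, config$metrics$min_overlap)
  soma <- compartment_mask(roi_lab, compartment = "soma")
  bg <- !soma
  contrast <- if (any(soma)) cnr(roi_v, roi_a = soma, roi_b = bg) else NULL
  geom <- config$geometry
  budget <- photons_per_pixel_scan(geom$n_projections,
                                   geom$photons_per_pixel_projection,
                                   length(geom$d1_mm))
  report <- list(
    sensitivity = sens[c("S", "TP", "T", "truth_cells", "truth_found")],
    cnr = if (!is.null(contrast))
      unclass(contrast)[c("I1", "I2", "sigma1", "sigma2", "cnr")],
    n_objects = nrow(seg$objects),
    photons_per_pixel_scan = budget$photons,
    photons_per_pixel_scan_1e6 = budget$photons_1e6,
    roi_start = as.integer(start - 1L), roi_shape = as.integer(shape))

  write_volume(roi_v, file.path(config$out_dir, "roi_intensity.mhd"))
  write_volume(seg$labels, file.path(config$out_dir, "roi_labels.tif"),
               dtype = "uint16")
  utils::write.csv(seg$objects, file.path(config$out_dir, "objects.csv"),
                   row.names = FALSE)
  write_metrics_report(report, file.path(config$out_dir, "report.json"))
  manifest <- list(
    config_checksum = config_checksum(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("nanoholo")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    photons_per_pixel_scan = budget$photons,
    stages = c("phantom", "prescan", "roi", "segment", "evaluate"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(config$out_dir, "config.json"))
  plog(config, "done: S = %s, %d object(s)",
       format(sens$S), nrow(seg$objects))
  out <- config$out_dir
  attr(out, "report") <- report
  attr(out, "manifest") <- manifest
  invisible(out)
}
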