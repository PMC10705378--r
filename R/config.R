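#' Quantification pipeline parameters
#'
#' Collects the tunable parameters of the compartment pipeline. Defaults are
#' calibrated on the synthetic generator: the closing (10 iterations of a
#' 3 px disk at 3 um/px, i.e. ~90 um reach) seals typical inter-vessel gaps
#' while leaving the ~1.5 mm well open, and the 0.2 mm^2 minimum hole area
#' excludes any unclosed gel lacunae from well candidacy.
#'
#' @param pixel_size_um Image sampling (um per pixel).
#' @param threshold_method `"otsu"` or `"manual"` vasculature threshold.
#' @param manual_threshold Raw threshold when `threshold_method = "manual"`.
#' @param n_iterations Dilate/erode iterations of the well-closing step.
#' @param element_radius_px Disk radius (px) of the structuring element.
#' @param min_hole_area_um2 Minimum well candidate area.
#' @param well_dilation_um Dilation applied to the detected well.
#' @param min_separation_um Minimum spot separation for detection.
#' @param prominence Normalized intensity cut-off for spot detection.
#' @return A named list of class `quant_config`.
#' @export
quant_config <- function(pixel_size_um = 3,
                         threshold_method = "otsu",
                         manual_threshold = NULL,
                         n_iterations = 10,
                         element_radius_px = 3,
                         min_hole_area_um2 = 2e5,
                         well_dilation_um = 20,
                         min_separation_um = 12,
                         prominence = 0.65) {
  structure(list(pixel_size_um = pixel_size_um,
                 threshold_method = threshold_method,
                 manual_threshold = manual_threshold,
                 n_iterations = n_iterations,
                 element_radius_px = element_radius_px,
                 min_hole_area_um2 = min_hole_area_um2,
                 well_dilation_um = well_dilation_um,
                 min_separation_um = min_separation_um,
                 prominence = prominence),
            class = "quant_config")
}

#' Read and validate a flat YAML run configuration
#'
#' Strict parsing: every key in the file must be a known parameter (the
#' union of [quant_config()], [device_geometry()] and the model/runtime keys
#' below), otherwise the first offending key is reported and nothing is run.
#' Unspecified keys fall back to the package defaults, and the fully
#' resolved configuration (defaults materialized) is what the run functions
#' echo into their output directory, so a run never depends on hidden
#' defaults.
#'
#' Recognized model/runtime keys: `dx_um`, `dt_h`, `bins`, `min_cells`,
#' `chi_max`, `n_boot`, `seed`, `out_dir`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `run_config`: list with `geometry` ([device_geometry()]),
#'   `image` ([quant_config()]), `model` (named list) and `run` (seed,
#'   out_dir).
#' @export
read_run_config <- function(path = NULL) {
  geom_keys <- c("gel_channel_length_um", "roi_width_um", "roi_height_um",
                 "well_diameter_um", "vessel_diameter_um", "pixel_size_um")
  image_keys <- setdiff(names(formals(quant_config)), "pixel_size_um")
  model_keys <- c("dx_um", "dt_h", "bins", "min_cells", "chi_max", "n_boot")
  run_keys <- c("seed", "out_dir")

  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_run_config: no such file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    known <- c(geom_keys, image_keys, model_keys, run_keys)
    bad <- setdiff(names(user), known)
    if (length(bad)) {
      stop("read_run_config: unknown configuration key '", bad[1], "'")
    }
  }
  pick <- function(keys, defaults) {
    out <- defaults
    for (k in intersect(keys, names(user))) out[[k]] <- user[[k]]
    out
  }
  # default field is the 3 x 3 mm vascular-bed ROI; the gel-channel length
  # applies to the migration-device arms
  geom_args <- pick(geom_keys, list(gel_channel_length_um = 1300,
                                    roi_width_um = 3000, roi_height_um = 3000,
                                    well_diameter_um = 1500,
                                    vessel_diameter_um = 40,
                                    pixel_size_um = 3))
  geometry <- do.call(device_geometry, geom_args)
  image_args <- pick(image_keys, formals(quant_config)[image_keys])
  image_args <- lapply(image_args, function(v) if (is.name(v)) NULL else v)
  image <- do.call(quant_config, c(image_args[!vapply(image_args, is.null, TRUE)],
                                   list(pixel_size_um = geometry$pixel_size_um)))
  model <- pick(model_keys, list(dx_um = NULL, dt_h = NULL, bins = 26,
                                 min_cells = 30, chi_max = NULL, n_boot = 0))
  run <- pick(run_keys, list(seed = 1, out_dir = "results"))
  structure(list(geometry = geometry, image = image, model = model, run = run),
            class = "run_config")
}

#' Write the fully resolved configuration next to the run outputs
#'
#' @param config A `run_config` from [read_run_config()].
#' @param dir Output directory.
#' @return Invisibly, the path of the echoed YAML file.
#' @export
echo_run_config <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- c(unclass(config$geometry),
            unclass(config$image)[setdiff(names(config$image), "pixel_size_um")],
            config$model, config$run)
  flat <- flat[!vapply(flat, is.null, TRUE)]
  path <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(flat, path)
  invisible(path)
}
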