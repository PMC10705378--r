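#' Device geometry for gel-channel and vascular-bed assays
#'
#' Physical dimensions, in microns, of the microfluidic geometry that
#' parameterize both the synthetic generators and the quantification
#' pipeline. Two stock layouts are used throughout: the unidirectional
#' migration device (gel channel 1300 um along the migration axis, imaged in
#' 2200 x 1300 um regions of interest) and the vascular-bed ("iVas") device
#' imaged as a 3 x 3 mm square field with a ~1.5 mm central well punched for
#' spheroid or tissue insertion. Self-assembled microvessels in these beds
#' have a typical diameter of 40 um.
#'
#' @param gel_channel_length_um Length of the gel channel along the
#'   migration axis (x); origin x = 0 sits at the monocyte-entry
#'   (endothelial) interface.
#' @param roi_width_um,roi_height_um Imaged field of view.
#' @param well_diameter_um Diameter of the central well.
#' @param vessel_diameter_um Target microvessel width.
#' @param pixel_size_um Image sampling (um per pixel).
#'
#' @return An object of class `device_geometry` (a named list of the above).
#' @examples
#' migration_geometry()
#' ivas_geometry()
#' @export
device_geometry <- function(gel_channel_length_um = 1300,
                            roi_width_um = 2200,
                            roi_height_um = 1300,
                            well_diameter_um = 1000,
                            vessel_diameter_um = 40,
                            pixel_size_um = 3) {
  g <- list(
    gel_channel_length_um = gel_channel_length_um,
    roi_width_um = roi_width_um,
    roi_height_um = roi_height_um,
    well_diameter_um = well_diameter_um,
    vessel_diameter_um = vessel_diameter_um,
    pixel_size_um = pixel_size_um
  )
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("device_geometry: '", nm, "' must be a single positive finite number")
    }
  }
  if (g$well_diameter_um >= min(g$roi_width_um, g$roi_height_um)) {
    stop("device_geometry: well_diameter_um must be smaller than the field of view")
  }
  if (g$vessel_diameter_um / g$pixel_size_um < 3) {
    stop("device_geometry: vessels are not resolvable; ",
         "vessel_diameter_um / pixel_size_um must be >= 3")
  }
  structure(g, class = "device_geometry")
}

#' @rdname device_geometry
#' @export
migration_geometry <- function(pixel_size_um = 3) {
  device_geometry(gel_channel_length_um = 1300,
                  roi_width_um = 2200, roi_height_um = 1300,
                  well_diameter_um = 1290,  # unused in migration devices
                  pixel_size_um = pixel_size_um)
}

#' @rdname device_geometry
#' @export
ivas_geometry <- function(pixel_size_um = 3) {
  device_geometry(gel_channel_length_um = 1300,
                  roi_width_um = 3000, roi_height_um = 3000,
                  well_diameter_um = 1500,
                  pixel_size_um = pixel_size_um)
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("Device geometry (um):\n")
  cat(sprintf("  gel channel length : %g\n", x$gel_channel_length_um))
  cat(sprintf("  ROI                : %g x %g\n", x$roi_width_um, x$roi_height_um))
  cat(sprintf("  central well diam. : %g\n", x$well_diameter_um))
  cat(sprintf("  vessel diam.       : %g\n", x$vessel_diameter_um))
  cat(sprintf("  pixel size         : %g um/px\n", x$pixel_size_um))
  invisible(x)
}

is_device_geometry <- function(x) inherits(x, "device_geometry")

assert_geometry <- function(geometry) {
  if (!is_device_geometry(geometry)) {
    stop("expected a 'device_geometry' object; see device_geometry()")
  }
  geometry
}
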