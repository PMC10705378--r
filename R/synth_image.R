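#' Generate a synthetic vascular-bed image with labelled monocytes
#'
#' Produces a two-channel image emulating a confocal max-projection of a
#' self-assembled microvascular network surrounding a central well, together
#' with full ground truth, so the quantification pipeline can be validated
#' without microscopy data.
#'
#' The vessel texture is procedural: random seed points are tessellated into
#' Voronoi regions and the region boundaries — a connected, capillary-like
#' mesh — are dilated to the target vessel width. Vessels are cleared from a
#' central disk of `well_diameter_um` (the spheroid well). Monocytes are
#' rendered as isotropic Gaussian intensity bumps (FWHM 12 um, the scale of
#' a CellTracker-labelled monocyte) at positions consistent with their
#' compartment labels:
#' \describe{
#'   \item{luminal}{cell centre inside the vessel mask,}
#'   \item{recruited}{inside the central well,}
#'   \item{extravasated}{in the gel, outside both.}
#' }
#' Cell centres keep a margin of one cell radius from compartment borders
#' and a minimum mutual separation of two spot widths. Gaussian read-out
#' noise is added at the requested signal-to-noise ratio (peak spot / vessel
#' amplitude divided by noise standard deviation).
#'
#' @param geometry A [device_geometry()]; [ivas_geometry()] matches the
#'   3 x 3 mm vascular-bed field.
#' @param n_luminal,n_extravasated,n_recruited Number of cells per
#'   compartment.
#' @param snr Signal-to-noise ratio (> 0).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   bundles.
#' @param mean_lacuna_um Typical spacing of the vessel mesh (centre-to-centre
#'   distance of avascular gaps).
#' @param spot_fwhm_um Full width at half maximum of a rendered cell.
#'
#' @return A `synthetic_image_bundle`: list with
#'   \item{image}{array `[rows, cols, 2]`, channel 1 vasculature, channel 2
#'     monocytes;}
#'   \item{pixel_size_um}{sampling;}
#'   \item{truth_vessel_mask, truth_well_mask}{logical matrices (disjoint);}
#'   \item{truth_cells}{data frame `x_px, y_px, x_um, y_um, compartment`
#'     (pixel indices 1-based, x = column, y = row; microns from the
#'     top-left corner).}
#' @examples
#' b <- generate_vessel_image(ivas_geometry(pixel_size_um = 6),
#'                            n_luminal = 5, n_extravasated = 5,
#'                            n_recruited = 5, snr = 10, seed = 1)
#' table(b$truth_cells$compartment)
#' @export
generate_vessel_image <- function(geometry,
                                  n_luminal,
                                  n_extravasated,
                                  n_recruited,
                                  snr = 10,
                                  seed = 1,
                                  mean_lacuna_um = 170,
                                  spot_fwhm_um = 12) {
  assert_geometry(geometry)
  counts <- c(luminal = as.numeric(n_luminal)[1],
              extravasated = as.numeric(n_extravasated)[1],
              recruited = as.numeric(n_recruited)[1])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("generate_vessel_image: cell counts must be nonnegative integers")
  }
  if (!is.numeric(snr) || snr <= 0) stop("generate_vessel_image: snr must be > 0")

  px <- geometry$pixel_size_um
  nx <- round(geometry$roi_width_um / px)
  ny <- round(geometry$roi_height_um / px)

  withr::with_seed(as.integer(seed), {
    masks <- make_vessel_masks(geometry, nx, ny, mean_lacuna_um)
    cells <- place_truth_cells(masks, counts, px, spot_fwhm_um)
    img <- render_channels(masks$vessel, cells, nx, ny, px, spot_fwhm_um, snr)
  })

  structure(
    list(image = img,
         pixel_size_um = px,
         truth_vessel_mask = masks$vessel,
         truth_well_mask = masks$well,
         truth_cells = cells),
    class = "synthetic_image_bundle"
  )
}

# Voronoi-edge vessel mesh plus a vessel-free central well disk.
make_vessel_masks <- function(geometry, nx, ny, mean_lacuna_um) {
  px <- geometry$pixel_size_um
  n_seeds <- max(4L, round(nx * ny * px^2 / mean_lacuna_um^2))
  sx <- sample.int(nx, n_seeds, replace = TRUE)
  sy <- sample.int(ny, n_seeds, replace = TRUE)
  seeds <- matrix(0L, ny, nx)
  seeds[cbind(sy, sx)] <- seq_len(n_seeds)
  # Flat image + large lambda => Euclidean Voronoi tessellation.
  lab <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(matrix(0, ny, nx)), seeds, lambda = 1e8))
  edge <- matrix(FALSE, ny, nx)
  edge[-ny, ] <- edge[-ny, ] | (lab[-1, ] != lab[-ny, ])
  edge[, -nx] <- edge[, -nx] | (lab[, -1] != lab[, -nx])
  # Ribbons of the target width around the edge set.
  half_w <- geometry$vessel_diameter_um / 2 / px
  d_to_edge <- EBImage::imageData(EBImage::distmap(1 - edge))
  vessel <- d_to_edge <= half_w

  cy <- (ny + 1) / 2
  cx <- (nx + 1) / 2
  r_well <- geometry$well_diameter_um / 2 / px
  dy <- (seq_len(ny) - cy)
  dx <- (seq_len(nx) - cx)
  dist2 <- outer(dy^2, dx^2, `+`)
  well <- dist2 <= r_well^2
  vessel[well] <- FALSE
  list(vessel = vessel, well = well)
}

# Rejection-sample cell centres per compartment with a margin of one cell
# radius from compartment borders and pairwise separation >= 2 spot widths.
place_truth_cells <- function(masks, counts, px, spot_fwhm_um) {
  margin_px <- max(1L, ceiling(spot_fwhm_um / 2 / px))
  brush <- EBImage::makeBrush(2L * margin_px + 1L, "disc")
  er <- function(m) EBImage::imageData(EBImage::erode(m * 1, brush)) > 0.5
  outside <- !(masks$vessel | masks$well)
  allowed <- list(
    luminal = er(masks$vessel),
    extravasated = er(outside),
    recruited = er(masks$well)
  )
  min_sep_px <- 2 * spot_fwhm_um / px
  xs <- numeric(0); ys <- numeric(0); labs <- character(0)
  for (comp in names(counts)) {
    n <- counts[[comp]]
    if (n == 0) next
    ok <- which(allowed[[comp]])
    if (length(ok) == 0) {
      stop("generate_vessel_image: no room to place any '", comp, "' cell")
    }
    nrow_m <- nrow(allowed[[comp]])
    placed <- 0L
    misses <- 0L       # consecutive rejections signal a saturated compartment
    while (placed < n) {
      if (misses > 2000L) {
        stop("generate_vessel_image: could not place ", n, " '", comp,
             "' cells with minimum separation; reduce counts for this ",
             "compartment")
      }
      idx <- ok[sample.int(length(ok), 1L)]
      y <- ((idx - 1L) %% nrow_m) + 1L
      x <- ((idx - 1L) %/% nrow_m) + 1L
      if (length(xs) &&
          min((xs - x)^2 + (ys - y)^2) < min_sep_px^2) {
        misses <- misses + 1L
        next
      }
      xs <- c(xs, x); ys <- c(ys, y); labs <- c(labs, comp)
      placed <- placed + 1L
      misses <- 0L
    }
  }
  data.frame(x_px = xs, y_px = ys,
             x_um = (xs - 0.5) * px, y_um = (ys - 0.5) * px,
             compartment = labs, stringsAsFactors = FALSE)
}

render_channels <- function(vessel, cells, nx, ny, px, spot_fwhm_um, snr) {
  amp <- 1
  noise_sd <- amp / snr
  vess_ch <- vessel * amp
  vess_ch <- EBImage::imageData(EBImage::gblur(vess_ch, sigma = 1))
  vess_ch <- vess_ch + matrix(stats::rnorm(nx * ny, sd = noise_sd), ny, nx)

  mono_ch <- matrix(0, ny, nx)
  if (nrow(cells)) {
    sigma_px <- spot_fwhm_um / (2 * sqrt(2 * log(2))) / px
    r <- ceiling(4 * sigma_px)
    off <- (-r):r
    kern <- exp(-outer(off^2, off^2, `+`) / (2 * sigma_px^2)) * amp
    for (i in seq_len(nrow(cells))) {
      ry <- cells$y_px[i] + off
      rx <- cells$x_px[i] + off
      sel_y <- ry >= 1 & ry <= ny
      sel_x <- rx >= 1 & rx <= nx
      mono_ch[ry[sel_y], rx[sel_x]] <-
        mono_ch[ry[sel_y], rx[sel_x]] + kern[sel_y, sel_x]
    }
  }
  mono_ch <- mono_ch + matrix(stats::rnorm(nx * ny, sd = noise_sd), ny, nx)
  array(c(vess_ch, mono_ch), dim = c(ny, nx, 2L),
        dimnames = list(NULL, NULL, c("vasculature", "monocytes")))
}

#' @export
print.synthetic_image_bundle <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Synthetic vascular-bed image: %d x %d px (%.3g um/px), 2 channels\n",
              d[1], d[2], x$pixel_size_um))
  print(table(x$truth_cells$compartment))
  invisible(x)
}

#' Write a synthetic image bundle to disk
#'
#' Writes the two-channel image as a channel-major multi-page TIFF, the
#' ground-truth vessel and well masks as single-page binary TIFFs, and the
#' true cell table as CSV.
#'
#' @param bundle A [generate_vessel_image()] result.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_image_bundle <- function(bundle, dir, prefix = "bundle") {
  stopifnot(inherits(bundle, "synthetic_image_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm01 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) matrix(0, nrow(m), ncol(m)) else (m - rng[1]) / diff(rng)
  }
  paths <- c(
    image = file.path(dir, paste0(prefix, "_image.tif")),
    vessel_mask = file.path(dir, paste0(prefix, "_vessel_mask.tif")),
    well_mask = file.path(dir, paste0(prefix, "_well_mask.tif")),
    truth_cells = file.path(dir, paste0(prefix, "_truth_cells.csv"))
  )
  tiff::writeTIFF(list(norm01(bundle$image[, , 1]), norm01(bundle$image[, , 2])),
                  paths["image"], bits.per.sample = 16L)
  tiff::writeTIFF(bundle$truth_vessel_mask * 1, paths["vessel_mask"])
  tiff::writeTIFF(bundle$truth_well_mask * 1, paths["well_mask"])
  utils::write.csv(bundle$truth_cells, paths["truth_cells"], row.names = FALSE)
  invisible(paths)
}
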