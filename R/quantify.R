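#' Collapse a confocal z-stack to a max projection
#'
#' Per-pixel maximum over z; the compartment analysis operates on this 2D
#' projection.
#'
#' @param stack 3D array `[rows, cols, z]` (or a 2D matrix, returned as is).
#' @return A 2D matrix.
#' @export
collapse_zstack <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    stop("collapse_zstack: expected a [rows, cols, z] array with >= 1 plane")
  }
  apply(stack, c(1, 2), max)
}

#' Segment the vasculature channel into a binary mask
#'
#' Thresholds the vasculature channel; pixels at or above the threshold are
#' vessel. The default Otsu threshold is computed on the min-max normalized
#' image (and is therefore invariant to affine intensity changes); a manual
#' threshold is applied on the raw intensity scale.
#'
#' @param channel 2D intensity matrix.
#' @param method `"otsu"` or `"manual"`.
#' @param manual_threshold Raw-intensity threshold, required when
#'   `method = "manual"`.
#' @param pixel_size_um Sampling, carried on the mask.
#' @return A `vessel_mask`: logical matrix with attribute `pixel_size_um`.
#' @export
segment_vasculature <- function(channel, method = c("otsu", "manual"),
                                manual_threshold = NULL, pixel_size_um = 1) {
  method <- match.arg(method)
  if (!is.matrix(channel) || length(channel) == 0) {
    stop("segment_vasculature: channel must be a non-empty matrix")
  }
  if (method == "manual") {
    if (is.null(manual_threshold) || !is.numeric(manual_threshold)) {
      stop("segment_vasculature: manual method requires manual_threshold")
    }
    mask <- channel >= manual_threshold
  } else {
    rng <- range(channel)
    if (diff(rng) == 0) {
      mask <- matrix(FALSE, nrow(channel), ncol(channel))
    } else {
      norm <- (channel - rng[1]) / diff(rng)
      thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
      mask <- norm >= thr
    }
  }
  structure(mask, pixel_size_um = pixel_size_um, class = c("vessel_mask", "matrix"))
}

vessel_mask_from_logical <- function(mask, pixel_size_um) {
  structure(mask, pixel_size_um = pixel_size_um,
            class = c("vessel_mask", "matrix"))
}

#' Locate the central well by morphological closing
#'
#' Reproduces the closing-based well search: the vessel mask is dilated
#' `n_iterations` times and then eroded the same number of times with a disk
#' structuring element, which closes the small dark inter-vessel gaps of the
#' extracellular matrix without closing the much larger central well. The
#' closed image is inverted; interior background components (those not
#' touching the image border) with area at least `min_hole_area_um2` are well
#' candidates and the largest is selected. The well is then dilated by
#' `well_dilation_um` so that cells sitting on the gel rim count as
#' recruited. A well-not-found error signals that closing failed or no well
#' is present.
#'
#' @param mask A [segment_vasculature()] result.
#' @param n_iterations Number of dilations (= number of erosions), >= 1.
#' @param min_hole_area_um2 Minimum well area (default 0.2 mm^2).
#' @param well_dilation_um Dilation of the detected well before
#'   classification.
#' @param element_radius_px Disk radius of the structuring element.
#' @return A list with
#'   \item{well}{`well_region`: logical matrix, plus `area_um2` and
#'     `centroid_px` attributes;}
#'   \item{vessels_outside_well}{the *original* vessel mask restricted to
#'     the complement of the dilated well, used for the luminal test.}
#' @export
find_central_well <- function(mask, n_iterations = 10,
                              min_hole_area_um2 = 2e5,
                              well_dilation_um = 20,
                              element_radius_px = 3) {
  if (!inherits(mask, "vessel_mask")) {
    stop("find_central_well: mask must come from segment_vasculature()")
  }
  if (n_iterations < 1) stop("find_central_well: n_iterations must be >= 1")
  px <- attr(mask, "pixel_size_um")
  m <- unclass(mask) * 1
  brush <- EBImage::makeBrush(2L * element_radius_px + 1L, "disc")
  for (i in seq_len(n_iterations)) m <- EBImage::imageData(EBImage::dilate(m, brush))
  for (i in seq_len(n_iterations)) m <- EBImage::imageData(EBImage::erode(m, brush))
  closed <- m > 0.5

  holes <- EBImage::imageData(EBImage::bwlabel(!closed * 1))
  if (max(holes) == 0) {
    stop("find_central_well: well not found (no background component; ",
         "closing may have failed or no well is present)")
  }
  border_labels <- unique(c(holes[1, ], holes[nrow(holes), ],
                            holes[, 1], holes[, ncol(holes)]))
  areas <- tabulate(holes[holes > 0], nbins = max(holes))
  areas_um2 <- areas * px^2
  candidates <- setdiff(which(areas_um2 >= min_hole_area_um2), border_labels)
  if (length(candidates) == 0) {
    stop("find_central_well: well not found (no interior hole >= ",
         min_hole_area_um2, " um^2)")
  }
  well_label <- candidates[which.max(areas_um2[candidates])]
  hole <- holes == well_label

  dil_px <- max(0L, round(well_dilation_um / px))
  well <- if (dil_px > 0) {
    EBImage::imageData(EBImage::dilate(hole * 1,
      EBImage::makeBrush(2L * dil_px + 1L, "disc"))) > 0.5
  } else hole

  idx <- which(well, arr.ind = TRUE)
  well_region <- structure(well,
    pixel_size_um = px,
    area_um2 = sum(well) * px^2,
    centroid_px = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
    class = c("well_region", "matrix"))

  vessels_outside <- vessel_mask_from_logical(unclass(mask) & !well, px)
  list(well = well_region, vessels_outside_well = vessels_outside)
}

#' Detect fluorescent cell spots as intensity maxima
#'
#' Find-Maxima style detector. The channel is min-max normalized to
#' \[0, 1\]; local maxima within a radius of `min_separation_um` whose
#' normalized intensity is at least `prominence` above the image minimum are
#' kept. Surviving candidates are accepted greedily in order of decreasing
#' intensity (ties broken by row, then column), enforcing the pairwise
#' separation. Detection is invariant to affine intensity rescaling by
#' construction; a constant image yields an empty spot set.
#'
#' @param channel 2D intensity matrix.
#' @param min_separation_um Minimum pairwise spot distance (> 0).
#' @param prominence Normalized intensity cut-off in (0, 1), the analogue of
#'   the Find-Maxima noise tolerance.
#' @param pixel_size_um Sampling.
#' @return A `spot_set`: data frame `x_px, y_px, peak_intensity` (1-based
#'   pixel indices, x = column, y = row) with attribute `pixel_size_um`.
#' @export
detect_spots <- function(channel, min_separation_um = 12, prominence = 0.65,
                         pixel_size_um = 1) {
  if (!is.matrix(channel)) stop("detect_spots: channel must be a matrix")
  if (!(prominence > 0 && prominence < 1)) {
    stop("detect_spots: prominence must be in (0, 1)")
  }
  if (min_separation_um <= 0) stop("detect_spots: min_separation_um must be > 0")
  empty <- data.frame(x_px = integer(0), y_px = integer(0),
                      peak_intensity = numeric(0))
  rng <- range(channel)
  if (diff(rng) == 0) {
    return(structure(empty, pixel_size_um = pixel_size_um,
                     class = c("spot_set", "data.frame")))
  }
  norm <- (channel - rng[1]) / diff(rng)
  sep_px <- min_separation_um / pixel_size_um
  r <- max(1L, floor(sep_px))
  brush <- EBImage::makeBrush(2L * r + 1L, "disc")
  local_max <- EBImage::imageData(EBImage::dilate(norm, brush))
  cand <- which(norm >= local_max - 1e-12 & norm >= prominence, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(structure(empty, pixel_size_um = pixel_size_um,
                     class = c("spot_set", "data.frame")))
  }
  vals <- norm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep_y <- numeric(0); keep_x <- numeric(0); keep_v <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    y <- cand[i, 1]; x <- cand[i, 2]
    if (length(keep_y) &&
        min((keep_y - y)^2 + (keep_x - x)^2) < sep_px^2) next
    keep_y <- c(keep_y, y); keep_x <- c(keep_x, x); keep_v <- c(keep_v, vals[i])
  }
  spots <- data.frame(x_px = as.integer(keep_x), y_px = as.integer(keep_y),
                      peak_intensity = keep_v)
  structure(spots, pixel_size_um = pixel_size_um,
            class = c("spot_set", "data.frame"))
}

#' Classify detected monocytes into compartments
#'
#' A spot inside the well mask is `recruited`; otherwise, inside the vessel
#' mask it is `luminal`; otherwise `extravasated`. The well takes precedence
#' over the vessel mask. The luminal test should use the original
#' (unclosed) vessel mask restricted outside the well, as returned by
#' [find_central_well()], because the closed mask contains filled gel gaps
#' that are not lumen.
#'
#' @param spots A [detect_spots()] result.
#' @param vessels A `vessel_mask`.
#' @param well A `well_region` (or `NULL` for devices without a well, in
#'   which case no spot is recruited).
#' @return A `compartment_counts`: list with `luminal`, `extravasated`,
#'   `recruited`, `total`, `recruited_fraction` and a `labels` character
#'   vector (one per spot, in input order).
#' @export
classify_compartments <- function(spots, vessels, well = NULL) {
  if (!inherits(spots, "spot_set")) {
    stop("classify_compartments: spots must come from detect_spots()")
  }
  n <- nrow(spots)
  labels <- character(n)
  if (n > 0) {
    idx <- cbind(spots$y_px, spots$x_px)
    in_well <- if (is.null(well)) rep(FALSE, n) else unclass(well)[idx]
    in_vessel <- unclass(vessels)[idx]
    labels <- ifelse(in_well, "recruited",
                     ifelse(in_vessel, "luminal", "extravasated"))
  }
  counts <- c(luminal = sum(labels == "luminal"),
              extravasated = sum(labels == "extravasated"),
              recruited = sum(labels == "recruited"))
  structure(
    list(luminal = unname(counts["luminal"]),
         extravasated = unname(counts["extravasated"]),
         recruited = unname(counts["recruited"]),
         total = n,
         recruited_fraction = if (n > 0) unname(counts["recruited"]) / n else 0,
         labels = labels),
    class = "compartment_counts")
}

#' @export
print.compartment_counts <- function(x, ...) {
  cat(sprintf("Compartment counts: %d luminal, %d extravasated, %d recruited (total %d)\n",
              x$luminal, x$extravasated, x$recruited, x$total))
  cat(sprintf("  recruited fraction: %.3f\n", x$recruited_fraction))
  invisible(x)
}

#' Run the full compartment pipeline on one two-channel image
#'
#' Max projection (if a z-stack is supplied per channel), vasculature
#' segmentation, well search, spot detection and compartment classification.
#'
#' @param vasculature Vasculature channel (matrix or z-stack array).
#' @param monocytes Monocyte channel (matrix or z-stack array).
#' @param config A [quant_config()] list of pipeline parameters.
#' @return A list with `counts` ([classify_compartments()] result), `spots`,
#'   `well`, `vessels` and `vessels_outside_well`.
#' @export
quantify_image <- function(vasculature, monocytes, config = quant_config()) {
  vase <- collapse_zstack(vasculature)
  mono <- collapse_zstack(monocytes)
  vessels <- segment_vasculature(vase, method = config$threshold_method,
                                 manual_threshold = config$manual_threshold,
                                 pixel_size_um = config$pixel_size_um)
  wr <- find_central_well(vessels,
                          n_iterations = config$n_iterations,
                          min_hole_area_um2 = config$min_hole_area_um2,
                          well_dilation_um = config$well_dilation_um,
                          element_radius_px = config$element_radius_px)
  spots <- detect_spots(mono, min_separation_um = config$min_separation_um,
                        prominence = config$prominence,
                        pixel_size_um = config$pixel_size_um)
  counts <- classify_compartments(spots, wr$vessels_outside_well, wr$well)
  list(counts = counts, spots = spots, well = wr$well, vessels = vessels,
       vessels_outside_well = wr$vessels_outside_well)
}

#' Compartment counts across a time course of images
#'
#' Runs [quantify_image()] per (device, day); a failing image (e.g. well not
#' found) is recorded as a flagged row rather than aborting the batch.
#'
#' @param images A list of entries, each a list with elements `vasculature`,
#'   `monocytes` and optionally `device_id` and `day`.
#' @param config A [quant_config()].
#' @return A data frame with one row per image: `device_id, day, luminal,
#'   extravasated, recruited, total, recruited_fraction, flags`.
#' @export
recruitment_timecourse <- function(images, config = quant_config()) {
  if (length(images) == 0) stop("recruitment_timecourse: need >= 1 image")
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    dev <- if (!is.null(im$device_id)) im$device_id else sprintf("device%d", i)
    day <- if (!is.null(im$day)) im$day else i
    res <- tryCatch(quantify_image(im$vasculature, im$monocytes, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(device_id = dev, day = day, luminal = NA_integer_,
                 extravasated = NA_integer_, recruited = NA_integer_,
                 total = NA_integer_, recruited_fraction = NA_real_,
                 flags = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      ct <- res$counts
      data.frame(device_id = dev, day = day, luminal = ct$luminal,
                 extravasated = ct$extravasated, recruited = ct$recruited,
                 total = ct$total, recruited_fraction = ct$recruited_fraction,
                 flags = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Circle-equivalent diameter of a spheroid mask
#'
#' Fits the spheroid outline by area: returns `2 * sqrt(area / pi)` in um,
#' the diameter of the circle with the same area as the mask.
#'
#' @param spheroid_mask Logical (or 0/1) 2D mask with one foreground
#'   component.
#' @param pixel_size_um Sampling.
#' @return Diameter in um.
#' @examples
#' m <- outer(-120:120, -120:120, function(y, x) x^2 + y^2 <= 100^2)
#' spheroid_equivalent_diameter(m, pixel_size_um = 1)  # ~200
#' @export
spheroid_equivalent_diameter <- function(spheroid_mask, pixel_size_um = 1) {
  area_px <- sum(spheroid_mask > 0)
  if (area_px == 0) stop("spheroid_equivalent_diameter: empty mask")
  2 * sqrt(area_px * pixel_size_um^2 / pi)
}
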