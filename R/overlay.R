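#' Write a labelled QC overlay of a quantified image
#'
#' Renders the vasculature channel in grey, the detected well outline in
#' blue, and detected spots coloured by compartment (luminal green,
#' extravasated yellow, recruited red) as a PNG, for visual inspection of a
#' [quantify_image()] run.
#'
#' @param vasculature Vasculature channel matrix (raw intensities).
#' @param result A [quantify_image()] result.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_qc_overlay <- function(vasculature, result, path) {
  vase <- collapse_zstack(vasculature)
  rng <- range(vase)
  grey <- if (diff(rng) == 0) vase * 0 else (vase - rng[1]) / diff(rng)
  r <- grey; g <- grey; b <- grey

  well <- unclass(result$well)
  inner <- EBImage::imageData(EBImage::erode(well * 1,
    EBImage::makeBrush(5, "disc"))) > 0.5
  ring <- well & !inner
  r[ring] <- 0.1; g[ring] <- 0.4; b[ring] <- 1

  spots <- result$spots
  labels <- result$counts$labels
  if (nrow(spots)) {
    cols <- list(luminal = c(0, 1, 0), extravasated = c(1, 1, 0),
                 recruited = c(1, 0.1, 0.1))
    for (i in seq_len(nrow(spots))) {
      yy <- pmax(1, pmin(nrow(grey), spots$y_px[i] + (-2:2)))
      xx <- pmax(1, pmin(ncol(grey), spots$x_px[i] + (-2:2)))
      cl <- cols[[labels[i]]]
      r[yy, xx] <- cl[1]; g[yy, xx] <- cl[2]; b[yy, xx] <- cl[3]
    }
  }
  img <- array(c(r, g, b), dim = c(nrow(grey), ncol(grey), 3))
  png::writePNG(img, path)
  invisible(path)
}
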