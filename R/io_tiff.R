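#' Read a multi-page TIFF into vasculature and monocyte channels
#'
#' Convenience reader for channel-major multi-page TIFFs (as written by
#' [write_image_bundle()] or exported from acquisition software). Channel
#' assignment is by page index from the configuration; pixel size always
#' comes from the supplied config (acquisition metadata varies too much
#' across exporters to trust silently).
#'
#' @param path TIFF path.
#' @param vasculature_channel,monocyte_channel 1-based page indices.
#' @return A list with matrices `vasculature` and `monocytes`, ready for
#'   [quantify_image()].
#' @export
read_image_channels <- function(path, vasculature_channel = 1,
                                monocyte_channel = 2) {
  if (!file.exists(path)) stop("read_image_channels: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- length(pages)
  if (vasculature_channel > n || monocyte_channel > n) {
    stop("read_image_channels: file has ", n, " page(s); channel indices ",
         vasculature_channel, "/", monocyte_channel, " out of range")
  }
  as_gray <- function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples per pixel
    p
  }
  list(vasculature = as_gray(pages[[vasculature_channel]]),
       monocytes = as_gray(pages[[monocyte_channel]]))
}
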