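# Shared fixtures, built once per test run.

# A synthetic vascular-bed bundle reused by several image tests
# (3 um/px, 1000 x 1000 px field).
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_vessel_image(ivas_geometry(pixel_size_um = 3),
                                      n_luminal = 30, n_extravasated = 40,
                                      n_recruited = 30, snr = 10, seed = 7)
    }
    cache
  }
})

fixture_config <- function(...) quant_config(pixel_size_um = 3, ...)

# Nearest-truth matching of detected spots (<= tol px) -> data frame of
# matched (detected label index, truth index).
match_spots <- function(spots, truth, tol_px = 3) {
  if (nrow(spots) == 0 || nrow(truth) == 0) {
    return(data.frame(spot = integer(0), truth = integer(0)))
  }
  d2 <- outer(spots$y_px, truth$y_px, "-")^2 +
    outer(spots$x_px, truth$x_px, "-")^2
  nn <- apply(d2, 1, which.min)
  ok <- sqrt(d2[cbind(seq_len(nrow(spots)), nn)]) <= tol_px
  data.frame(spot = which(ok), truth = nn[ok])
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
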