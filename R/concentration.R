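#' Chemoattractant concentration profiles along the gel channel
#'
#' Builds the normalized chemoattractant field c(x) used by both the
#' migration simulator and the Keller-Segel solver. Concentration is
#' dimensionless in \[0, 1\]: conditioned-media experiments compare
#' conditions rather than absolute molar levels, so chi carries units of
#' um^2/h per unit normalized concentration.
#'
#' Three profiles cover the experimental arms:
#' \describe{
#'   \item{`zero`}{no chemoattractant anywhere (control arm), c = 0.}
#'   \item{`uniform`}{conditioned media on both sides of the gel
#'     (chemokinesis arm), c = 1 with zero gradient.}
#'   \item{`linear_gradient`}{conditioned media in the channel opposite the
#'     monocyte entry (chemotaxis arm), c(x) = x / L rising toward the
#'     source.}
#' }
#'
#' @param geometry A [device_geometry()].
#' @param profile_kind One of `"zero"`, `"uniform"`, `"linear_gradient"`.
#' @param n_points Number of grid points spanning \[0, L\].
#'
#' @return A `concentration_field`: list with `x_grid_um`, `c`,
#'   `profile_kind` and the constant spatial gradient `dcdx_per_um`.
#' @examples
#' conc <- make_concentration(migration_geometry(), "linear_gradient")
#' conc$dcdx_per_um  # 1 / 1300 per um
#' @export
make_concentration <- function(geometry, profile_kind, n_points = 201) {
  assert_geometry(geometry)
  kinds <- c("zero", "uniform", "linear_gradient")
  if (!is.character(profile_kind) || length(profile_kind) != 1L ||
      !(profile_kind %in% kinds)) {
    stop("make_concentration: profile_kind must be one of ",
         paste(sQuote(kinds), collapse = ", "))
  }
  L <- geometry$gel_channel_length_um
  x <- seq(0, L, length.out = n_points)
  c_vals <- switch(profile_kind,
    zero = rep(0, n_points),
    uniform = rep(1, n_points),
    linear_gradient = x / L
  )
  dcdx <- if (profile_kind == "linear_gradient") 1 / L else 0
  structure(
    list(x_grid_um = x, c = c_vals, profile_kind = profile_kind,
         dcdx_per_um = dcdx, gel_channel_length_um = L),
    class = "concentration_field"
  )
}

is_concentration_field <- function(x) inherits(x, "concentration_field")

assert_concentration <- function(conc) {
  if (!is_concentration_field(conc)) {
    stop("expected a 'concentration_field' object; see make_concentration()")
  }
  conc
}

# Gradient dc/dx (per um) evaluated at arbitrary positions. The stock
# profiles have a spatially constant gradient; this keeps the simulator and
# solver correct should a custom piecewise field ever be supplied.
conc_gradient_at <- function(conc, x) {
  if (length(conc$c) < 2L) return(rep(0, length(x)))
  if (!is.null(conc$dcdx_per_um)) return(rep(conc$dcdx_per_um, length(x)))
  g <- diff(conc$c) / diff(conc$x_grid_um)
  idx <- findInterval(x, conc$x_grid_um, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(g))
  g[idx]
}
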