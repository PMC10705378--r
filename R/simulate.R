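#' Keller-Segel parameter pair (D, chi)
#'
#' Bundles the random-motility (diffusion) coefficient D and the chemotaxis
#' coefficient chi of the one-dimensional Keller-Segel cell-flux model
#' J = -D dn/dx + chi n dc/dx. Concentration c is normalized to \[0, 1\], so
#' chi is expressed in um^2/h per unit normalized concentration; the drift
#' induced by a field with gradient dc/dx is v = chi * dc/dx (um/h).
#'
#' @param D_um2_per_h Random-motility coefficient (um^2/h, >= 0).
#' @param chi_um2_per_h Chemotaxis coefficient (um^2/h per unit
#'   concentration); 0 means purely random motility.
#' @return A `ks_parameters` object.
#' @examples
#' ks_parameters(D_um2_per_h = 1000, chi_um2_per_h = 13000)
#' @export
ks_parameters <- function(D_um2_per_h, chi_um2_per_h = 0) {
  if (!is.numeric(D_um2_per_h) || length(D_um2_per_h) != 1L ||
      !is.finite(D_um2_per_h) || D_um2_per_h < 0) {
    stop("ks_parameters: D_um2_per_h must be a single finite number >= 0")
  }
  if (!is.numeric(chi_um2_per_h) || length(chi_um2_per_h) != 1L ||
      !is.finite(chi_um2_per_h)) {
    stop("ks_parameters: chi_um2_per_h must be a single finite number")
  }
  structure(list(D_um2_per_h = D_um2_per_h, chi_um2_per_h = chi_um2_per_h),
            class = "ks_parameters")
}

#' Simulate endpoint positions of migrating monocytes
#'
#' Microscopic counterpart of the Keller-Segel model: each cell performs a
#' biased random walk along the gel channel, integrated with the
#' Euler-Maruyama scheme
#' `x <- x + chi * dcdx(x) * dt + sqrt(2 * D * dt) * N(0, 1)`,
#' with reflecting boundaries at x = 0 (the monocyte-entry endothelial
#' interface, where cells accumulate before migrating) and x = L (the far
#' gel wall). All cells start at x = 0 at t = 0 (seeding).
#'
#' @param params A [ks_parameters()].
#' @param conc A [make_concentration()] field supplying the local gradient.
#' @param geometry A [device_geometry()].
#' @param n_cells Number of cells (>= 1).
#' @param times_h Snapshot times in hours (sorted ascending internally).
#' @param dt_h Integration step; must keep the per-step diffusive
#'   displacement `sqrt(2 D dt)` below L / 20.
#' @param seed Integer seed; fixed seed gives identical snapshots.
#' @param condition_label,device_id,roi_id Provenance carried into the
#'   snapshots.
#'
#' @return A list of `migration_snapshot` objects (one per time), each a
#'   list with `positions_um`, `time_h`, `condition_label`, `roi_id`,
#'   `device_id`.
#' @examples
#' geom <- migration_geometry()
#' conc <- make_concentration(geom, "zero")
#' snaps <- simulate_migration(ks_parameters(1000), conc, geom,
#'                             n_cells = 100, times_h = 24, seed = 1)
#' mean(snaps[[1]]$positions_um)
#' @export
simulate_migration <- function(params, conc, geometry, n_cells,
                               times_h, dt_h = 0.01, seed = 1,
                               condition_label = "synthetic",
                               device_id = "sim", roi_id = "roi1") {
  if (!inherits(params, "ks_parameters")) {
    stop("simulate_migration: params must be ks_parameters()")
  }
  assert_concentration(conc)
  assert_geometry(geometry)
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("simulate_migration: n_cells must be >= 1")
  }
  if (any(!is.finite(times_h)) || any(times_h <= 0)) {
    stop("simulate_migration: times_h must be positive and finite")
  }
  L <- geometry$gel_channel_length_um
  D <- params$D_um2_per_h
  chi <- params$chi_um2_per_h
  if (sqrt(2 * D * dt_h) >= L / 20) {
    stop("simulate_migration: dt_h too large; sqrt(2 D dt) must be < L / 20")
  }
  times_h <- sort(unique(times_h))
  n_cells <- as.integer(n_cells)

  snapshots <- withr::with_seed(as.integer(seed), {
    x <- rep(0, n_cells)
    t_now <- 0
    const_grad <- !is.null(conc$dcdx_per_um)
    sd_step <- sqrt(2 * D * dt_h)
    out <- vector("list", length(times_h))
    for (k in seq_along(times_h)) {
      n_steps <- round((times_h[k] - t_now) / dt_h)
      for (s in seq_len(n_steps)) {
        drift <- if (const_grad) chi * conc$dcdx_per_um else
          chi * conc_gradient_at(conc, x)
        x <- x + drift * dt_h
        if (D > 0) x <- x + stats::rnorm(n_cells, sd = sd_step)
        x <- reflect_into(x, L)
      }
      t_now <- t_now + n_steps * dt_h
      out[[k]] <- structure(
        list(positions_um = x, time_h = times_h[k],
             condition_label = condition_label,
             roi_id = roi_id, device_id = device_id),
        class = "migration_snapshot")
    }
    out
  })
  snapshots
}

# Fold positions back into [0, L] (mirror reflection, repeated for large
# excursions).
reflect_into <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Assemble a migration snapshot from observed positions
#'
#' @param positions_um Cell x-coordinates (um), origin at the monocyte-entry
#'   interface.
#' @param time_h Elapsed time since seeding (> 0).
#' @param geometry A [device_geometry()]; positions must lie in
#'   \[0, gel_channel_length_um\].
#' @param condition_label,roi_id,device_id Provenance.
#' @return A `migration_snapshot` object.
#' @export
migration_snapshot <- function(positions_um, time_h, geometry,
                               condition_label = "observed",
                               roi_id = "roi1", device_id = "dev1") {
  assert_geometry(geometry)
  if (!is.numeric(time_h) || length(time_h) != 1L || time_h <= 0) {
    stop("migration_snapshot: time_h must be a single positive number")
  }
  L <- geometry$gel_channel_length_um
  if (any(!is.finite(positions_um)) ||
      any(positions_um < 0) || any(positions_um > L)) {
    stop("migration_snapshot: positions must be finite and within [0, L]")
  }
  structure(list(positions_um = as.numeric(positions_um), time_h = time_h,
                 condition_label = condition_label,
                 roi_id = roi_id, device_id = device_id),
            class = "migration_snapshot")
}

#' Write / read migration snapshots as CSV
#'
#' Long format with one row per cell:
#' `device_id, roi_id, condition_label, time_h, position_um`.
#'
#' @param snapshots A list of `migration_snapshot` objects (or a single one).
#' @param path CSV path.
#' @return `write_snapshots` returns `path` invisibly; `read_snapshots`
#'   returns a list of `migration_snapshot` objects, one per
#'   (device, roi, condition, time) combination.
#' @export
write_snapshots <- function(snapshots, path) {
  if (inherits(snapshots, "migration_snapshot")) snapshots <- list(snapshots)
  rows <- lapply(snapshots, function(s) {
    data.frame(device_id = s$device_id, roi_id = s$roi_id,
               condition_label = s$condition_label, time_h = s$time_h,
               position_um = s$positions_um, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshots
#' @param geometry A [device_geometry()] used to validate positions on read.
#' @export
read_snapshots <- function(path, geometry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device_id", "roi_id", "condition_label", "time_h", "position_um")
  if (!all(need %in% names(df))) {
    stop("read_snapshots: CSV must have columns ", paste(need, collapse = ", "))
  }
  key <- interaction(df$device_id, df$roi_id, df$condition_label, df$time_h,
                     drop = TRUE)
  lapply(split(df, key), function(d) {
    migration_snapshot(d$position_um, d$time_h[1], geometry,
                       condition_label = d$condition_label[1],
                       roi_id = d$roi_id[1], device_id = d$device_id[1])
  })
}
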