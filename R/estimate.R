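#' Estimate the random-motility coefficient D from control snapshots
#'
#' Fits D to endpoint positions from devices without a chemoattractant
#' gradient (control or uniform arms). Two estimators:
#' \describe{
#'   \item{moment}{`D_hat = mean(x^2 / (2 t))` pooled over all cells, the
#'     mean-squared-displacement identity for diffusion from a reflecting
#'     origin. Valid while the diffusion length stays below a quarter
#'     channel (`sqrt(2 D t) < L / 4`); beyond that the far boundary biases
#'     the moment and a validity flag is set.}
#'   \item{likelihood}{bins positions into `bins` equal intervals over
#'     \[0, L\] and maximizes the multinomial log-likelihood of the bin
#'     counts under the [solve_forward()] prediction (chi = 0), by Brent
#'     search on log10(D).}
#' }
#'
#' @param control_snapshots A `migration_snapshot` or list of them; all from
#'   zero- or uniform-concentration conditions.
#' @param geometry A [device_geometry()].
#' @param estimator `"moment"` or `"likelihood"`.
#' @param bins Number of equal-width bins for the likelihood estimator.
#' @param min_cells Minimum pooled cell count (insufficient-data error
#'   below it).
#' @param D_bounds Search bounds for D (um^2/h) in the likelihood fit.
#' @param dx_um Solver grid spacing (passed to [solve_forward()]).
#' @param n_boot Bootstrap replicates (resampling cells within snapshots)
#'   for a standard error; 0 skips it.
#' @param boot_seed Seed for the bootstrap.
#' @return A `fit_result`: list with `estimate`, `objective` (final negative
#'   log-likelihood; `NA` for the moment estimator), `converged`,
#'   `n_cells_used`, `stderr` (or `NA`), `flags` (character vector).
#' @export
estimate_D <- function(control_snapshots, geometry,
                       estimator = c("moment", "likelihood"),
                       bins = 26, min_cells = 30,
                       D_bounds = c(1, 1e5), dx_um = NULL,
                       n_boot = 0, boot_seed = 1) {
  estimator <- match.arg(estimator)
  assert_geometry(geometry)
  snaps <- as_snapshot_list(control_snapshots)
  n_used <- sum(vapply(snaps, function(s) length(s$positions_um), 0L))
  if (n_used < min_cells) {
    stop("estimate_D: insufficient data (", n_used, " cells < ", min_cells, ")")
  }
  L <- geometry$gel_channel_length_um
  flags <- character(0)

  fit_once <- function(snaps) {
    if (estimator == "moment") {
      x2_over_2t <- unlist(lapply(snaps, function(s) {
        s$positions_um^2 / (2 * s$time_h)
      }))
      est <- mean(x2_over_2t)
      list(estimate = est, objective = NA_real_, converged = TRUE)
    } else {
      breaks <- seq(0, L, length.out = bins + 1)
      counts <- lapply(snaps, function(s) {
        tabulate(findInterval(s$positions_um, breaks,
                              rightmost.closed = TRUE, all.inside = TRUE),
                 nbins = bins)
      })
      times <- vapply(snaps, function(s) s$time_h, 0)
      conc0 <- make_concentration(geometry, "zero")
      nll <- function(log10D) {
        D <- 10^log10D
        obj <- 0
        for (t_h in unique(times)) {
          field <- solve_forward(ks_parameters(D), conc0, geometry,
                                 t_end_h = t_h, dx_um = dx_um)
          p <- pmax(density_bin_masses(field, breaks), 1e-12)
          p <- p / sum(p)
          for (j in which(times == t_h)) {
            obj <- obj - sum(counts[[j]] * log(p))
          }
        }
        obj
      }
      opt <- stats::optimize(nll, interval = log10(D_bounds), tol = 1e-4)
      est <- 10^opt$minimum
      at_bound <- min(abs(opt$minimum - log10(D_bounds))) < 1e-3
      list(estimate = est, objective = opt$objective, converged = !at_bound)
    }
  }

  main <- fit_once(snaps)
  t_max <- max(vapply(snaps, function(s) s$time_h, 0))
  if (sqrt(2 * main$estimate * t_max) >= L / 4 && estimator == "moment") {
    flags <- c(flags, "moment_validity: diffusion length >= L/4; estimate biased by far boundary")
  }
  stderr <- NA_real_
  if (n_boot > 0) {
    boots <- withr::with_seed(as.integer(boot_seed), {
      vapply(seq_len(n_boot), function(b) {
        res <- lapply(snaps, function(s) {
          s$positions_um <- sample(s$positions_um, replace = TRUE)
          s
        })
        fit_once(res)$estimate
      }, 0)
    })
    stderr <- stats::sd(boots)
  }
  fit_result(main$estimate, main$objective, main$converged, n_used, stderr, flags)
}

#' Pool control D estimates into a single value
#'
#' Unweighted mean of converged control fits; random motility is taken as
#' constant across devices, so this single value is held fixed in every chi
#' fit.
#'
#' @param fits A list of `fit_result` objects (or bare numbers).
#' @return The pooled D (um^2/h).
#' @examples
#' pool_D(list(900, 1100))  # 1000
#' @export
pool_D <- function(fits) {
  if (length(fits) == 0) stop("pool_D: no fits supplied")
  vals <- vapply(fits, function(f) {
    if (is.numeric(f)) return(as.numeric(f))
    if (!inherits(f, "fit_result")) stop("pool_D: expected fit_result objects")
    if (!isTRUE(f$converged)) stop("pool_D: all fits must have converged")
    f$estimate
  }, 0)
  mean(vals)
}

#' Estimate the chemotaxis coefficient chi with D held fixed
#'
#' Subtracts the random-motility contribution: D is frozen at the pooled
#' control value and only chi is fit, by maximizing the binned multinomial
#' likelihood of the observed positions under [solve_forward()] predictions.
#' Brent search over `chi` in `[-chi_max, chi_max]`; a negative estimate
#' means repulsion. Requires a condition with a nonzero gradient — in a
#' uniform or zero field chi does not enter the model and is unidentifiable
#' (that arm is the chemokinesis comparison, see [compare_chemokinesis()]).
#'
#' @param snapshots A `migration_snapshot` or list of them (one condition).
#' @param D_fixed Pooled control D (um^2/h, > 0).
#' @param conc A [make_concentration()] field with nonzero gradient.
#' @param geometry A [device_geometry()].
#' @param bins,min_cells As in [estimate_D()].
#' @param chi_max Search half-width; default corresponds to a maximal drift
#'   displacement of two channel lengths over the latest snapshot time,
#'   `chi_max = 2 L^2 / t_max` for the linear 0-to-1 gradient.
#' @param dx_um Solver grid spacing.
#' @return A `fit_result` with additional element
#'   `effective_drift_um_per_h = estimate * max|dc/dx|`.
#' @export
estimate_chi <- function(snapshots, D_fixed, conc, geometry,
                         bins = 26, min_cells = 30, chi_max = NULL,
                         dx_um = NULL) {
  assert_geometry(geometry)
  assert_concentration(conc)
  if (!is.numeric(D_fixed) || D_fixed <= 0) {
    stop("estimate_chi: D_fixed must be > 0")
  }
  gmax <- max(abs(conc_gradient_at(conc, conc$x_grid_um)))
  if (gmax == 0) {
    stop("estimate_chi: chi is unidentifiable under a zero/uniform ",
         "concentration (no gradient); use compare_chemokinesis() for that arm")
  }
  snaps <- as_snapshot_list(snapshots)
  n_used <- sum(vapply(snaps, function(s) length(s$positions_um), 0L))
  if (n_used < min_cells) {
    stop("estimate_chi: insufficient data (", n_used, " cells < ", min_cells, ")")
  }
  L <- geometry$gel_channel_length_um
  times <- vapply(snaps, function(s) s$time_h, 0)
  if (is.null(chi_max)) chi_max <- 2 * L^2 / max(times)

  breaks <- seq(0, L, length.out = bins + 1)
  counts <- lapply(snaps, function(s) {
    tabulate(findInterval(s$positions_um, breaks,
                          rightmost.closed = TRUE, all.inside = TRUE),
             nbins = bins)
  })
  nll <- function(chi) {
    obj <- 0
    for (t_h in unique(times)) {
      field <- solve_forward(ks_parameters(D_fixed, chi), conc, geometry,
                             t_end_h = t_h, dx_um = dx_um)
      p <- pmax(density_bin_masses(field, breaks), 1e-12)
      p <- p / sum(p)
      for (j in which(times == t_h)) obj <- obj - sum(counts[[j]] * log(p))
    }
    obj
  }
  opt <- stats::optimize(nll, interval = c(-chi_max, chi_max),
                         tol = max(1e-6, chi_max * 1e-5))
  at_bound <- min(abs(opt$minimum - c(-chi_max, chi_max))) < chi_max * 1e-3
  out <- fit_result(opt$minimum, opt$objective, !at_bound, n_used)
  out$effective_drift_um_per_h <- opt$minimum * gmax
  out
}

#' Percentage of monocytes past the channel midline
#'
#' The migrating-monocyte readout of unidirectional gel-channel assays:
#' `100 * #(x > L/2) / total`; cells exactly at L/2 count as not migrated.
#'
#' @param snapshot A `migration_snapshot` with at least one cell.
#' @param geometry A [device_geometry()].
#' @return Percentage in \[0, 100\].
#' @export
migrating_percentage <- function(snapshot, geometry) {
  assert_geometry(geometry)
  if (!inherits(snapshot, "migration_snapshot")) {
    stop("migrating_percentage: expected a migration_snapshot")
  }
  x <- snapshot$positions_um
  if (length(x) == 0) stop("migrating_percentage: empty snapshot")
  100 * sum(x > geometry$gel_channel_length_um / 2) / length(x)
}

fit_result <- function(estimate, objective, converged, n_cells_used,
                       stderr = NA_real_, flags = character(0)) {
  structure(list(estimate = estimate, objective = objective,
                 converged = converged, n_cells_used = n_cells_used,
                 stderr = stderr, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit: estimate = %.4g (n = %d cells, converged: %s)\n",
              x$estimate, x$n_cells_used, x$converged))
  if (!is.na(x$stderr)) cat(sprintf("  bootstrap SE: %.3g\n", x$stderr))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

as_snapshot_list <- function(x) {
  if (inherits(x, "migration_snapshot")) return(list(x))
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "migration_snapshot"))) {
    stop("expected a migration_snapshot or a list of them")
  }
  x
}

#' Discriminate chemotaxis from chemokinesis across assay arms
#'
#' Compares the three experimental arms of the unidirectional migration
#' assay: `control` (no chemoattractant), `uniform` (conditioned media on
#' both sides — any motility increase here is chemokinesis, a gradient-free
#' stimulation of random motility), and `gradient` (conditioned media in the
#' far channel only). Computes the migrating percentage per ROI in each arm,
#' estimates D separately for the control and uniform arms (chemokinesis
#' manifests as `D_uniform > D_control` with chi unidentifiable), and fits
#' chi for the gradient arm.
#'
#' Which D is held fixed in the gradient-arm chi fit is set by `d_policy`:
#' `"control"` uses the pooled control D (the default subtraction logic when
#' chemokinesis is absent); `"auto"` (default) switches to the uniform-arm D
#' when `D_uniform / D_control > chemokinesis_ratio`, since under
#' chemokinesis the stimulated arms share the elevated motility and fixing
#' the unstimulated D would misread the extra spread as outward drift;
#' `"uniform"` always uses the uniform-arm D.
#'
#' @param gradient_snapshots,uniform_snapshots,control_snapshots Lists of
#'   `migration_snapshot` objects (one per ROI).
#' @param geometry A [device_geometry()].
#' @param conc_gradient Concentration field of the gradient arm (default
#'   linear 0 to 1 over the channel).
#' @param estimator D estimator, as in [estimate_D()].
#' @param d_policy `"auto"`, `"control"` or `"uniform"` (see above).
#' @param chemokinesis_ratio Ratio threshold for the `"auto"` switch.
#' @param ... Passed to [estimate_D()] and [estimate_chi()].
#' @return A `chemokinesis_report`: list with per-arm `percentages`,
#'   `D_control`, `D_uniform`, `D_ratio`, `chi_fit` (a `fit_result`),
#'   `effective_drift_um_per_h`, `d_used_for_gradient` and `d_policy_used`.
#' @export
compare_chemokinesis <- function(gradient_snapshots, uniform_snapshots,
                                 control_snapshots, geometry,
                                 conc_gradient = NULL,
                                 estimator = "likelihood",
                                 d_policy = c("auto", "control", "uniform"),
                                 chemokinesis_ratio = 1.5, ...) {
  d_policy <- match.arg(d_policy)
  assert_geometry(geometry)
  arms <- list(gradient = as_snapshot_list(gradient_snapshots),
               uniform = as_snapshot_list(uniform_snapshots),
               control = as_snapshot_list(control_snapshots))
  if (is.null(conc_gradient)) {
    conc_gradient <- make_concentration(geometry, "linear_gradient")
  }
  percentages <- lapply(arms, function(snaps) {
    vapply(snaps, migrating_percentage, 0, geometry = geometry)
  })
  fit_arm <- function(snaps) {
    fits <- lapply(snaps, estimate_D, geometry = geometry,
                   estimator = estimator, ...)
    list(pooled = pool_D(fits), fits = fits)
  }
  Dc <- fit_arm(arms$control)
  Du <- fit_arm(arms$uniform)
  ratio <- Du$pooled / Dc$pooled

  D_used <- switch(d_policy,
    control = Dc$pooled,
    uniform = Du$pooled,
    auto = if (is.finite(ratio) && ratio > chemokinesis_ratio) Du$pooled else Dc$pooled
  )
  chi_fit <- estimate_chi(arms$gradient, D_fixed = D_used,
                          conc = conc_gradient, geometry = geometry, ...)
  structure(
    list(percentages = percentages,
         D_control = Dc$pooled, D_uniform = Du$pooled, D_ratio = ratio,
         D_control_fits = Dc$fits, D_uniform_fits = Du$fits,
         chi_fit = chi_fit,
         effective_drift_um_per_h = chi_fit$effective_drift_um_per_h,
         d_used_for_gradient = D_used, d_policy_used = d_policy),
    class = "chemokinesis_report")
}

#' @export
print.chemokinesis_report <- function(x, ...) {
  cat("Chemotaxis vs chemokinesis report\n")
  for (arm in names(x$percentages)) {
    cat(sprintf("  %% migrating (%s): mean %.1f over %d ROIs\n",
                arm, mean(x$percentages[[arm]]), length(x$percentages[[arm]])))
  }
  cat(sprintf("  D_control = %.4g, D_uniform = %.4g (ratio %.2f)\n",
              x$D_control, x$D_uniform, x$D_ratio))
  cat(sprintf("  chi_hat = %.4g (effective drift %.2f um/h; D fixed at %.4g)\n",
              x$chi_fit$estimate, x$effective_drift_um_per_h,
              x$d_used_for_gradient))
  invisible(x)
}
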