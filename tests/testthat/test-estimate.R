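geom <- migration_geometry()
conc0 <- make_concentration(geom, "zero")
concg <- make_concentration(geom, "linear_gradient")
L <- geom$gel_channel_length_um

test_that("moment estimator identities hold", {
  s0 <- migration_snapshot(rep(0, 50), 24, geom)
  expect_equal(estimate_D(s0, geom, "moment")$estimate, 0)

  withr::with_seed(13, {
    x <- pmin(abs(stats::rnorm(5000, 0, sqrt(2 * 1000 * 24))), L)
  })
  s <- migration_snapshot(x, 24, geom)
  fit <- estimate_D(s, geom, "moment")
  expect_lt(abs(fit$estimate / 1000 - 1), 0.05)

  # scaling all positions by 2 scales D by 4
  s2 <- migration_snapshot(pmin(2 * x, L), 24, geom)
  fit2 <- estimate_D(s2, geom, "moment")
  # (clipping at L touches almost no cells at this sd)
  expect_equal(fit2$estimate / fit$estimate, 4, tolerance = 0.02)

  expect_error(estimate_D(migration_snapshot(c(10, 20), 24, geom), geom),
               "insufficient")
})

test_that("moment and likelihood estimators agree on diffusive data", {
  s <- simulate_migration(ks_parameters(1000), conc0, geom, 5000,
                          times_h = 24, seed = 3)[[1]]
  m <- estimate_D(s, geom, "moment")
  l <- estimate_D(s, geom, "likelihood")
  expect_true(m$converged && l$converged)
  expect_lt(abs(m$estimate / l$estimate - 1), 0.10)
  expect_lt(abs(l$estimate / 1000 - 1), 0.10)
  expect_length(m$flags, 0)  # sqrt(2Dt) = 219 um << L/4
})

test_that("bootstrap standard errors are reproducible and sane", {
  s <- simulate_migration(ks_parameters(1000), conc0, geom, 1000,
                          times_h = 24, seed = 6)[[1]]
  f1 <- estimate_D(s, geom, "moment", n_boot = 50, boot_seed = 2)
  f2 <- estimate_D(s, geom, "moment", n_boot = 50, boot_seed = 2)
  expect_equal(f1$stderr, f2$stderr)
  # SE of a mean of 1000 squared half-normals: a few percent of D
  expect_gt(f1$stderr, 0.01 * f1$estimate)
  expect_lt(f1$stderr, 0.10 * f1$estimate)
})

test_that("pooling control fits averages converged estimates", {
  expect_equal(pool_D(list(1000)), 1000)
  expect_equal(pool_D(list(900, 1100)), 1000)
  expect_error(pool_D(list()), "no fits")

  fits <- lapply(1:10, function(r) {
    s <- simulate_migration(ks_parameters(1000), conc0, geom, 500,
                            times_h = 24, seed = 100 + r)[[1]]
    estimate_D(s, geom, "moment")
  })
  expect_lt(abs(pool_D(fits) / 1000 - 1), 0.05)

  bad <- fits[[1]]; bad$converged <- FALSE
  expect_error(pool_D(list(bad)), "converged")
})

test_that("chi is unidentifiable without a gradient", {
  s <- simulate_migration(ks_parameters(1000), conc0, geom, 100,
                          times_h = 24, seed = 1)[[1]]
  expect_error(estimate_chi(s, 1000, make_concentration(geom, "uniform"), geom),
               "unidentifiable")
  expect_error(estimate_chi(s, -1, concg, geom), "D_fixed")
})

test_that("chi recovery: null is tight and truth is recovered", {
  null_s <- simulate_migration(ks_parameters(1000, 0), concg, geom, 5000,
                               times_h = 24, seed = 17)[[1]]
  f0 <- estimate_chi(null_s, 1000, concg, geom)
  expect_lt(abs(f0$effective_drift_um_per_h), 2)

  s <- simulate_migration(ks_parameters(1000, 13000), concg, geom, 5000,
                          times_h = 24, seed = 18)[[1]]
  f <- estimate_chi(s, 1000, concg, geom)
  expect_true(f$converged)
  expect_lt(abs(f$estimate / 13000 - 1), 0.15)

  # repulsion (negative chi) presses cells against the origin and is
  # recovered with the right sign
  rep_s <- simulate_migration(ks_parameters(1000, -13000), concg, geom, 5000,
                              times_h = 24, seed = 19)[[1]]
  fr <- estimate_chi(rep_s, 1000, concg, geom)
  expect_lt(fr$estimate, 0)
})

test_that("null chi fits rarely escape the 2 um/h drift band", {
  drifts <- vapply(1:50, function(r) {
    s <- simulate_migration(ks_parameters(1000, 0), concg, geom, 400,
                            times_h = 24, seed = 300 + r)[[1]]
    estimate_chi(s, 1000, concg, geom)$effective_drift_um_per_h
  }, 0)
  expect_lte(mean(abs(drifts) > 2), 0.10)
})

test_that("migrating percentage counts strictly-past-midline cells", {
  expect_equal(migrating_percentage(
    migration_snapshot(c(0, 100, L / 2), 24, geom), geom), 0)
  expect_equal(migrating_percentage(
    migration_snapshot(rep(L / 2 + 1, 7), 24, geom), geom), 100)
  expect_error(migrating_percentage(
    migration_snapshot(numeric(0), 24, geom), geom), "empty")
})

test_that("chemokinesis report distinguishes the two mechanisms", {
  conc1 <- make_concentration(geom, "uniform")
  sim_arm <- function(D, chi, conc, off) lapply(1:2, function(r) {
    simulate_migration(ks_parameters(D, chi), conc, geom, 1200,
                       times_h = 24, seed = off + r,
                       roi_id = paste0("roi", r))[[1]]
  })
  # identical data in all arms: percentages equal, chi within the null band
  # (moment D estimator here; the likelihood path is exercised elsewhere)
  same <- sim_arm(1000, 0, conc0, 40)
  rep0 <- compare_chemokinesis(same, same, same, geom, conc_gradient = concg,
                               estimator = "moment")
  expect_equal(rep0$percentages$gradient, rep0$percentages$uniform)
  expect_equal(rep0$D_ratio, 1)
  expect_lt(abs(rep0$effective_drift_um_per_h), 2)

  # pure chemokinesis: stimulated arms at 2x D, no gradient response
  rep1 <- compare_chemokinesis(sim_arm(2000, 0, concg, 50),
                               sim_arm(2000, 0, conc1, 60),
                               sim_arm(1000, 0, conc0, 70),
                               geom, conc_gradient = concg,
                               estimator = "moment")
  expect_lt(abs(rep1$D_ratio - 2), 0.4)
  expect_lt(abs(rep1$effective_drift_um_per_h), 2)
  expect_equal(rep1$d_used_for_gradient, rep1$D_uniform)

  # true chemotaxis: gradient arm migrates more than uniform arm
  rep2 <- compare_chemokinesis(sim_arm(1000, 13000, concg, 80),
                               sim_arm(1000, 0, conc1, 80),
                               sim_arm(1000, 0, conc0, 90),
                               geom, conc_gradient = concg,
                               estimator = "moment")
  expect_gt(mean(rep2$percentages$gradient), mean(rep2$percentages$uniform))
  expect_gt(rep2$chi_fit$estimate, 0)
})
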