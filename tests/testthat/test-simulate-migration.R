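geom <- migration_geometry()
conc0 <- make_concentration(geom, "zero")
concg <- make_concentration(geom, "linear_gradient")
L <- geom$gel_channel_length_um

test_that("frozen dynamics keep every cell at the origin", {
  s <- simulate_migration(ks_parameters(0, 0), concg, geom,
                          n_cells = 100, times_h = 24, seed = 1)[[1]]
  expect_true(all(s$positions_um == 0))
})

test_that("pure diffusion matches half-normal moments", {
  D <- 1000; t_h <- 24; n <- 5000
  s <- simulate_migration(ks_parameters(D), conc0, geom,
                          n_cells = n, times_h = t_h, seed = 3)[[1]]
  x <- s$positions_um
  # reflected Brownian motion from 0 (far boundary negligible at 2Dt << L^2):
  # mean = sqrt(2 * (2Dt) / pi), second moment about 0 = 2Dt
  sigma2 <- 2 * D * t_h
  expect_lt(abs(mean(x) - sqrt(2 * sigma2 / pi)),
            3 * stats::sd(x) / sqrt(n))
  expect_lt(abs(mean(x^2) - sigma2),
            3 * stats::sd(x^2) / sqrt(n))
})

test_that("a chemotactic gradient shifts cells forward (paired seeds)", {
  base <- simulate_migration(ks_parameters(1000, 0), concg, geom,
                             n_cells = 5000, times_h = 24, seed = 5)[[1]]
  biased <- simulate_migration(ks_parameters(1000, 13000), concg, geom,
                               n_cells = 5000, times_h = 24, seed = 5)[[1]]
  expect_gt(mean(biased$positions_um), mean(base$positions_um))
})

test_that("reflection keeps a million cell-steps inside the channel", {
  # D large enough that excursions hit both walls often
  snaps <- simulate_migration(ks_parameters(2e4), conc0, geom,
                              n_cells = 1000, times_h = seq(1, 10), dt_h = 0.01,
                              seed = 9)
  for (s in snaps) {
    expect_true(all(s$positions_um >= 0 & s$positions_um <= L))
  }
})

test_that("snapshots are deterministic and carry provenance", {
  a <- simulate_migration(ks_parameters(800, 500), concg, geom, 200,
                          times_h = c(24, 48), seed = 11,
                          condition_label = "mcm_gradient",
                          device_id = "d1", roi_id = "r2")
  b <- simulate_migration(ks_parameters(800, 500), concg, geom, 200,
                          times_h = c(24, 48), seed = 11,
                          condition_label = "mcm_gradient",
                          device_id = "d1", roi_id = "r2")
  expect_identical(a, b)
  expect_equal(a[[2]]$time_h, 48)
  expect_equal(a[[1]]$roi_id, "r2")
})

test_that("invalid parameters and steps are rejected", {
  expect_error(ks_parameters(-5), "D_um2_per_h")
  expect_error(ks_parameters(1, NaN), "chi")
  # sqrt(2 D dt) must stay below L / 20
  expect_error(simulate_migration(ks_parameters(1e6), conc0, geom, 10,
                                  times_h = 1, dt_h = 1, seed = 1),
               "dt_h too large")
  expect_error(simulate_migration(ks_parameters(100), conc0, geom, 10,
                                  times_h = -1, seed = 1), "times_h")
})

test_that("snapshot CSVs round-trip", {
  snaps <- simulate_migration(ks_parameters(1000), conc0, geom, 50,
                              times_h = 24, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_snapshots(snaps, path)
  back <- read_snapshots(path, geom)
  expect_length(back, 1)
  expect_equal(sort(back[[1]]$positions_um), sort(snaps[[1]]$positions_um))
  expect_equal(back[[1]]$time_h, 24)
})
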