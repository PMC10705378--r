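test_that("z-stack collapse is the per-pixel maximum", {
  one <- matrix(runif(20 * 30), 20)
  expect_identical(collapse_zstack(one), one)

  two <- array(c(one, one + 1), dim = c(20, 30, 2))
  expect_equal(collapse_zstack(two), one + 1)

  withr::with_seed(4, {
    stack <- array(rnorm(10 * 12 * 5), dim = c(10, 12, 5))
  })
  proj <- collapse_zstack(stack)
  # brute-force pixel loop oracle
  for (i in 1:10) for (j in 1:12) {
    expect_identical(proj[i, j], max(stack[i, j, ]))
  }
  expect_error(collapse_zstack(array(1, dim = c(2, 2, 0))), "plane")
})

test_that("vasculature thresholding separates a bimodal image exactly", {
  expect_true(all(!segment_vasculature(matrix(0, 10, 10), method = "manual",
                                       manual_threshold = 1)))
  expect_error(segment_vasculature(matrix(1, 5, 5), method = "manual"),
               "manual_threshold")

  withr::with_seed(1, {
    img <- matrix(10, 50, 50)
    bright <- sample(length(img), 250)  # 10% at 200
    img[bright] <- 200
  })
  mask <- segment_vasculature(img, method = "otsu")
  expect_identical(which(mask), sort(bright))

  # exhaustive-sweep oracle: the threshold maximizing between-class variance
  # lies strictly between the two modes
  vals <- sort(unique(as.vector(img)))
  bcv <- vapply(vals[-length(vals)], function(t) {
    w1 <- mean(img <= t); w2 <- 1 - w1
    w1 * w2 * (mean(img[img <= t]) - mean(img[img > t]))^2
  }, 0)
  t_star <- vals[-length(vals)][which.max(bcv)]
  expect_equal(img > t_star, unclass(mask), ignore_attr = TRUE)

  # affine invariance of the otsu mask
  mask_off <- segment_vasculature(img + 37, method = "otsu")
  expect_identical(unclass(mask), unclass(mask_off))
  mask_scaled <- segment_vasculature(img * 5, method = "otsu")
  expect_identical(unclass(mask), unclass(mask_scaled))
})

test_that("the central well is recovered from the synthetic bundle", {
  b <- fixture_bundle()
  mask <- segment_vasculature(b$image[, , 1], pixel_size_um = b$pixel_size_um)
  wr <- find_central_well(mask)
  expect_gte(dice_coefficient(unclass(wr$well), b$truth_well_mask), 0.85)
  expect_equal(attr(wr$well, "area_um2"),
               sum(wr$well) * b$pixel_size_um^2)
  # luminal reference mask excludes the well
  expect_false(any(unclass(wr$vessels_outside_well) & unclass(wr$well)))

  # doubling iterations on already-closed gaps barely moves the well area
  wr2 <- find_central_well(mask, n_iterations = 20)
  expect_lt(abs(sum(wr2$well) - sum(wr$well)) / sum(wr$well), 0.05)
})

test_that("a gap-free mask has no well", {
  solid <- monorecruit:::vessel_mask_from_logical(matrix(TRUE, 120, 120), 5)
  expect_error(find_central_well(solid), "well not found")
})

test_that("spot detection recovers isolated Gaussians and is scale-invariant", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64))), 0)

  px <- 3
  withr::with_seed(21, {
    truth_y <- rep(seq(30, 310, by = 70), 5)
    truth_x <- rep(seq(30, 310, by = 70), each = 5)
    img <- matrix(0, 340, 340)
    sigma <- 12 / 2.355 / px
    off <- -8:8
    kern <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
    for (k in seq_along(truth_y)) {
      img[truth_y[k] + off, truth_x[k] + off] <-
        img[truth_y[k] + off, truth_x[k] + off] + kern
    }
    img <- img + matrix(rnorm(length(img), sd = 0.1), nrow(img))
  })
  spots <- detect_spots(img, min_separation_um = 12, prominence = 0.65,
                        pixel_size_um = px)
  expect_equal(nrow(spots), 25)
  m <- match_spots(spots, data.frame(y_px = truth_y, x_px = truth_x))
  expect_equal(nrow(m), 25)

  spots5 <- detect_spots(img * 5, min_separation_um = 12, prominence = 0.65,
                         pixel_size_um = px)
  expect_identical(spots$x_px, spots5$x_px)
  expect_identical(spots$y_px, spots5$y_px)

  expect_error(detect_spots(img, prominence = 1.2), "prominence")
})

test_that("compartment classification obeys precedence and conservation", {
  vessels <- monorecruit:::vessel_mask_from_logical(
    matrix(c(TRUE, FALSE), 10, 10), 1)
  well <- structure(matrix(FALSE, 10, 10), class = c("well_region", "matrix"))
  well[1:5, 1:5] <- TRUE

  empty <- detect_spots(matrix(0, 10, 10))
  ct0 <- classify_compartments(empty, vessels, well)
  expect_equal(c(ct0$luminal, ct0$extravasated, ct0$recruited, ct0$total), rep(0, 4))
  expect_equal(ct0$recruited_fraction, 0)

  spots <- structure(
    data.frame(x_px = c(2, 2, 8), y_px = c(1, 2, 2), peak_intensity = 1),
    pixel_size_um = 1, class = c("spot_set", "data.frame"))
  ct <- classify_compartments(spots, vessels, well)
  # (1,2) and (2,2) are inside the well (precedence over vessel); (2,8) is
  # on a vessel column outside the well... rows alternate TRUE/FALSE
  expect_equal(ct$total, 3)
  expect_equal(ct$luminal + ct$extravasated + ct$recruited, ct$total)
  expect_equal(ct$recruited, 2)

  all_in <- structure(
    data.frame(x_px = c(1, 2, 3), y_px = c(1, 2, 3), peak_intensity = 1),
    pixel_size_um = 1, class = c("spot_set", "data.frame"))
  ct2 <- classify_compartments(all_in, vessels, well)
  expect_equal(ct2$recruited, ct2$total)
  expect_equal(ct2$recruited_fraction, 1)
})

test_that("full-pipeline counts recover the generator's truth", {
  b <- fixture_bundle()
  res <- quantify_image(b$image[, , 1], b$image[, , 2], fixture_config())
  ct <- res$counts
  expect_equal(ct$luminal + ct$extravasated + ct$recruited, ct$total)

  truth <- table(factor(b$truth_cells$compartment,
                        c("luminal", "extravasated", "recruited")))
  got <- c(ct$luminal, ct$extravasated, ct$recruited)
  expect_true(all(abs(got - as.numeric(truth)) <= 0.10 * as.numeric(truth) + 1))

  # determinism of the whole pipeline
  res2 <- quantify_image(b$image[, , 1], b$image[, , 2], fixture_config())
  expect_identical(res2$counts[1:5], ct[1:5])
})

test_that("enlarging the well dilation never loses recruited cells", {
  b <- fixture_bundle()
  cfgs <- lapply(c(20, 50, 100), function(w) fixture_config(well_dilation_um = w))
  rec <- vapply(cfgs, function(cf) {
    quantify_image(b$image[, , 1], b$image[, , 2], cf)$counts$recruited
  }, 0)
  expect_true(all(diff(rec) >= 0))
})

test_that("time courses isolate failures and track recruitment", {
  g <- ivas_geometry(pixel_size_um = 6)
  days <- lapply(1:3, function(d) {
    b <- generate_vessel_image(g, 60 - 15 * d, 35, 5 + 15 * d,
                               snr = 10, seed = 30 + d)
    list(vasculature = b$image[, , 1], monocytes = b$image[, , 2],
         device_id = "dev1", day = d)
  })
  tab <- recruitment_timecourse(days, quant_config(pixel_size_um = 6))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$flags == ""))
  expect_true(all(diff(tab$recruited_fraction) > 0))
  expect_true(all(tab$luminal + tab$extravasated + tab$recruited == tab$total))

  # identical image supplied twice gives identical rows
  twice <- recruitment_timecourse(days[c(1, 1)], quant_config(pixel_size_um = 6))
  expect_equal(twice[1, 3:7], twice[2, 3:7], ignore_attr = TRUE)

  # one corrupt image is flagged without suppressing the others
  bad <- days
  bad[[2]]$vasculature <- matrix(1, 100, 100)  # solid: no well
  tab2 <- recruitment_timecourse(bad, quant_config(pixel_size_um = 6))
  expect_equal(sum(tab2$flags != ""), 1)
  expect_equal(sum(!is.na(tab2$total)), 2)
})

test_that("spheroid circle-equivalent diameter matches pixel counting", {
  disk <- outer(-120:120, -120:120, function(y, x) x^2 + y^2 <= 100^2)
  expect_equal(spheroid_equivalent_diameter(disk, 1), 200, tolerance = 0.01)

  # 2:1 ellipse with the same area -> same equivalent diameter
  a <- 100 * sqrt(2); b <- 100 / sqrt(2)
  ell <- outer(-160:160, -160:160, function(y, x) (x / a)^2 + (y / b)^2 <= 1)
  expect_equal(spheroid_equivalent_diameter(ell, 1),
               spheroid_equivalent_diameter(disk, 1), tolerance = 0.01)

  withr::with_seed(8, {
    blob <- EBImage::imageData(EBImage::dilate(
      matrix(runif(80 * 80) > 0.97, 80), EBImage::makeBrush(9, "disc"))) > 0.5
  })
  expect_equal(spheroid_equivalent_diameter(blob, 2),
               2 * sqrt(sum(blob) * 4 / pi))
  expect_error(spheroid_equivalent_diameter(matrix(FALSE, 5, 5)), "empty")
})
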