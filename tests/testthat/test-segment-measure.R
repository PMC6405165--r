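test_that("Otsu threshold separates a two-level image and rejects constants", {
  img <- matrix(c(0, 0, 10, 10), 2, 2)
  thr <- otsu_threshold(img)
  expect_true(thr >= 0 && thr < 10)
  expect_identical(img > thr, matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  # exhaustive scan oracle agrees, including the tie-break
  expect_equal(thr, otsu_scan_oracle(img))

  expect_error(otsu_threshold(matrix(5, 4, 4)), class = "es_degenerate_image")
})

test_that("Otsu equals the exhaustive between-class-variance scan on random images", {
  with_seed(20, {
    for (i in 1:100) {
      img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
      expect_equal(otsu_threshold(img), otsu_scan_oracle(img), tolerance = 1e-12)
    }
  })
})

test_that("dual-channel mask is the intersection of the per-channel foregrounds", {
  a <- disk_image(size = 40, radius = 8, cx = 15, cy = 20)
  b <- disk_image(size = 40, radius = 8, cx = 25, cy = 20)
  mask <- dual_channel_mask(a, b)
  manual <- (a > otsu_threshold(a)) & (b > otsu_threshold(b))
  expect_identical(unclass(mask)[, ], manual)

  # A intersected with itself is the single-channel foreground
  self_mask <- dual_channel_mask(a, a)
  expect_identical(unclass(self_mask)[, ], a > otsu_threshold(a))

  # a constant channel flags an empty mask instead of crashing
  flat <- matrix(100, 40, 40)
  empty <- dual_channel_mask(a, flat)
  expect_false(any(empty))
  expect_identical(attr(empty, "flag"), "degenerate channel")
})

test_that("masked statistics match closed forms and masking is idempotent", {
  img <- matrix(0, 3, 3)
  mask <- matrix(FALSE, 3, 3)
  img[1, 1:3] <- 2; mask[1, 1:3] <- TRUE
  m <- measure_masked(img, mask)
  expect_equal(m$mean, 2)
  expect_equal(m$median, 2)
  expect_equal(m$sd, 0)
  expect_equal(m$area, 3L)

  img2 <- matrix(c(1, 2, 3, 4), 2, 2)
  all_mask <- matrix(TRUE, 2, 2)
  m2 <- measure_masked(img2, all_mask)
  expect_equal(m2$mean, 2.5)
  expect_equal(m2$median, 2.5)
  expect_equal(m2$sd, 1.2909944487358056)  # sample SD of {1,2,3,4}

  # empty mask -> measurement unavailable
  m3 <- measure_masked(img2, matrix(FALSE, 2, 2))
  expect_true(is.na(m3$mean))
  expect_equal(m3$area, 0L)

  # idempotence: cropping to the mask leaves the masked statistics unchanged
  cropped <- img2
  cropped[!all_mask] <- 0
  expect_equal(measure_masked(cropped, all_mask), m2)
})

test_that("control-channel masking applies one channel's mask to both", {
  dir <- withr::local_tempdir()
  s <- small_fluor_sim(dir, seed = 37, ratios = c(a = 0.25), n_wells_each = 2)
  idx <- discover_series(dir, time_origin = 6, time_step = 120)
  meas <- quantify_series(idx, mask_channel = "red")
  # both channels report the same mask area at each well/timepoint/slice
  key <- paste(meas$well, meas$t_index, meas$z)
  areas <- split(meas$area, key)
  expect_true(all(vapply(areas, function(a) length(unique(a)) == 1, logical(1))))

  # the shared mask equals the red channel's own Otsu foreground
  well <- meas$well[1]
  g <- load_series(idx, well, "red", z = 0)
  expect_equal(meas$area[meas$well == well & meas$t_index == 0 &
                           meas$z == 0 & meas$channel == "red"],
               sum(g$frames[[1]] > otsu_threshold(g$frames[[1]])))

  expect_error(quantify_series(idx, mask_channel = "bf"),
               class = "es_image_error")
})

test_that("z-aggregation equals pooling all masked pixels", {
  one <- data.frame(mean = 5, median = 5, sd = 1, area = 10L)
  expect_equal(aggregate_z(one)$mean, 5)
  expect_equal(aggregate_z(one)$area, 10L)

  two <- data.frame(mean = c(2, 4), median = c(2, 4), sd = c(0, 0), area = c(7L, 7L))
  expect_equal(aggregate_z(two)$mean, 3)

  # random slice sets: aggregate equals the pooled-pixel computation
  with_seed(31, {
    for (rep in 1:20) {
      n_slices <- sample(2:5, 1)
      pixels <- lapply(seq_len(n_slices), function(z)
        stats::rnorm(sample(2:40, 1), mean = stats::runif(1, 0, 100), sd = 5))
      slices <- do.call(rbind, lapply(pixels, function(v)
        data.frame(mean = mean(v), median = stats::median(v),
                   sd = stats::sd(v), area = length(v))))
      agg <- aggregate_z(slices)
      pooled <- unlist(pixels)
      expect_equal(agg$mean, mean(pooled), tolerance = 1e-12)
      expect_equal(agg$sd, stats::sd(pooled), tolerance = 1e-10)
      expect_equal(agg$area, length(pooled))
    }
  })

  # all slices invalid -> timepoint missing
  none <- data.frame(mean = NA_real_, median = NA_real_, sd = NA_real_, area = 0L)
  expect_true(is.na(aggregate_z(none)$mean))
})

test_that("ratio-image measurement recovers programmed ratios and handles zeros", {
  # identical stacks: constant self-ratio measured as exactly 1 per slice
  stack <- list(disk_image(fg = 3000, bg = 200), disk_image(fg = 1500, bg = 200))
  self <- spim_ratio_measure(stack, stack)
  expect_equal(self$mean, c(1, 1))
  expect_true(all(self$degenerate))

  # programmed ratio 3 inside the embryo, noisy, 2 slices
  control <- lapply(c(1, 2), function(z)
    disk_image(size = 48, radius = 10, fg = 2000, bg = 400, noise_sd = 40, seed = 100 + z))
  test <- lapply(c(1, 2), function(z) {
    base <- disk_image(size = 48, radius = 10, fg = 6000, bg = 400, noise_sd = 40, seed = 200 + z)
    base
  })
  res <- spim_ratio_measure(test, control)
  expect_equal(nrow(res), 2)
  expect_equal(res$mean, c(3, 3), tolerance = 0.05)

  # zero-control pixels are excluded before masking; nothing non-finite leaks
  ctrl0 <- control[[1]]; ctrl0[1:5, 1:5] <- 0
  res0 <- spim_ratio_measure(test[1], list(ctrl0))
  expect_equal(res0$n_excluded, 25L)
  expect_true(all(is.finite(res0$mean)))

  # entirely-zero control slice is skipped and reported
  expect_message(resz <- spim_ratio_measure(test[1], list(matrix(0, 48, 48))),
                 "skipped")
  expect_equal(nrow(resz), 0)
  expect_equal(attr(resz, "skipped"), 1L)
})

test_that("ratio measurement is invariant to common positive rescaling", {
  control <- list(disk_image(fg = 2000, bg = 400, noise_sd = 30, seed = 9))
  test <- list(disk_image(fg = 5000, bg = 400, noise_sd = 30, seed = 10))
  base <- spim_ratio_measure(test, control)
  scaled <- spim_ratio_measure(lapply(test, `*`, 2.5), lapply(control, `*`, 2.5))
  expect_equal(scaled$mean, base$mean, tolerance = 1e-12)
  expect_equal(scaled$area, base$area)
})
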