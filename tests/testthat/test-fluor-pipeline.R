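make_trace <- function(times, values) data.frame(time_hpf = times, value = values)

test_that("ratiometric normalization divides by the reference at t_norm", {
  times <- c(9.5, 10.1, 11)
  test <- make_trace(times, c(4, 8, 6))
  ref <- make_trace(times, c(2, 2, 5))
  norm <- normalize_trace(test, ref, t_norm = 10)
  expect_equal(norm$value, c(2, 4, 3))
  expect_equal(attr(norm, "normalization_time"), 10.1)

  # self-normalization gives 1 at t_norm
  self <- normalize_trace(ref, ref, t_norm = 10)
  expect_equal(self$value[2], 1)

  # non-positive reference flags the well
  bad <- make_trace(times, c(2, 0, 5))
  expect_error(normalize_trace(test, bad, t_norm = 10), class = "es_negative_well")
})

test_that("normalization cancels injection-volume variation on simulated wells", {
  dir <- withr::local_tempdir()
  s <- small_fluor_sim(dir, seed = 23, ratios = c(a = 1.5), n_wells_each = 6)
  idx <- discover_series(dir, time_origin = 6, time_step = 120)
  agg <- aggregate_measurements(quantify_series(idx))
  tr <- build_traces(agg, s$layout, "green", "red", t_norm = 10)
  at_norm <- tr$traces[abs(tr$traces$time_hpf - 10) < 1e-9, ]
  expect_equal(nrow(at_norm), 6)
  expect_equal(unname(mean(at_norm$value)), 1.5, tolerance = 0.1)
  # normalized spread across wells far below the 30% volume CV
  expect_lt(stats::sd(at_norm$value) / mean(at_norm$value), 0.1)

  raw_red <- agg[agg$channel == "red" & abs(agg$time_hpf - 10) < 1e-9, ]
  expect_gt(stats::sd(raw_red$mean) / mean(raw_red$mean), 0.15)  # raw CV is large
})

test_that("QC keeps bright wells and drops simulated dead wells exactly", {
  dir <- withr::local_tempdir()
  layout <- randomize_layout(c(a = 8), rows = 2, cols = 4, seed = 29)
  config <- sim_config(plate_rows = 2, plate_cols = 4, image_size = 64,
                       t_start = 6, t_end = 14, t_step = 120, z_slices = 1,
                       channels = c("green", "red"), background_level = 1000,
                       noise_sd = 200, signal_level = 10000, embryo_radius = 12,
                       dead_well_fraction = 0.4, seed = 30)
  sim <- simulate_plate(config, layout,
                        list(condition_model("a", brightness = c(green = 1, red = 1))),
                        dir)
  expect_true(any(sim$wells$is_dead) && any(!sim$wells$is_dead))
  idx <- discover_series(dir, time_origin = 6, time_step = 120)
  agg <- aggregate_measurements(quantify_series(idx))
  qc <- qc_filter(agg, qc_params(), channel = "red")
  expect_setequal(qc$dropped$well, sim$wells$well[sim$wells$is_dead])
  expect_setequal(qc$kept, sim$wells$well[!sim$wells$is_dead])
  expect_true(all(grepl("no signal", qc$dropped$reason)))
})

test_that("plate fusion recovers hidden scale factors and is a fixed point", {
  times <- seq(6, 20, by = 1)
  base <- 2 * exp(-times / 30)
  make_plate <- function(factor) {
    rbind(
      data.frame(well = "A1", condition = "ctrl", time_hpf = times,
                 value = base * factor),
      data.frame(well = "A2", condition = "other", time_hpf = times,
                 value = 3 * base * factor)
    )
  }
  plates <- list(p1 = make_plate(1), p2 = make_plate(1.7), p3 = make_plate(0.4))
  fused <- fuse_plates(plates, "ctrl")
  s <- attr(fused, "scale_factors")
  expect_equal(unname(s), c(1, 1 / 1.7, 1 / 0.4), tolerance = 1e-9)

  # control curves coincide after fusion
  ctrl <- fused[fused$condition == "ctrl", ]
  spread <- tapply(ctrl$value, ctrl$time_hpf, function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))

  # fusing the fused plates again yields unit factors
  refused <- fuse_plates(split(fused, fused$plate), "ctrl")
  expect_equal(unname(attr(refused, "scale_factors")), rep(1, 3), tolerance = 1e-9)

  # single plate is returned unchanged with s = 1
  one <- fuse_plates(plates[1], "ctrl")
  expect_equal(unname(attr(one, "scale_factors")), 1)
  expect_equal(one$value, plates$p1$value)

  # missing control names the offending plate
  broken <- plates
  broken$p2 <- broken$p2[broken$p2$condition != "ctrl", ]
  err <- tryCatch(fuse_plates(broken, "ctrl"), error = identity)
  expect_s3_class(err, "es_fusion_error")
  expect_match(conditionMessage(err), "p2")
})

test_that("conditions are ranked by descending mean with alphabetical ties", {
  traces <- rbind(
    data.frame(well = "A1", condition = "B", time_hpf = 10, value = 3),
    data.frame(well = "A2", condition = "A", time_hpf = 10, value = 1),
    data.frame(well = "A3", condition = "D", time_hpf = 10, value = 2),
    data.frame(well = "A4", condition = "C", time_hpf = 10, value = 2)
  )
  rk <- rank_conditions(traces, t = 10)
  expect_equal(rk$condition, c("B", "C", "D", "A"))
  expect_equal(rk$n_wells, rep(1L, 4))
})

test_that("cross-species table pins class normalizers to their references", {
  window_means <- c(Venus = 4, YFPx = 8, eGFP = 2, Clover = 1, mRFP = 5, mScar = 10)
  references <- c(Venus = 1.2, eGFP = 1.0, mRFP = 0.6)
  classes <- c(Venus = "yellow", YFPx = "yellow", eGFP = "green",
               Clover = "green", mRFP = "red", mScar = "red")
  normalizers <- c(yellow = "Venus", green = "eGFP", red = "mRFP")
  tab <- cross_species_table(window_means, references, classes, normalizers)

  expect_equal(tab$normalized_internal[tab$condition == "Venus"], 1.2)
  expect_equal(tab$normalized_internal[tab$condition == "eGFP"], 1.0)
  # proportionality within a class: YFPx has twice the normalizer's mean
  expect_equal(tab$normalized_internal[tab$condition == "YFPx"], 2 * 1.2)

  # invariance to rescaling a whole class
  scaled <- window_means
  scaled[names(classes)[classes == "green"]] <-
    scaled[names(classes)[classes == "green"]] * 7
  tab2 <- cross_species_table(scaled, references, classes, normalizers)
  green <- tab$condition[tab$colour_class == "green"]
  expect_equal(tab2$normalized_internal[match(green, tab2$condition)],
               tab$normalized_internal[match(green, tab$condition)])

  # missing normalizer excludes the class with an error record
  tab3 <- cross_species_table(window_means[names(window_means) != "mRFP"],
                              references, classes, normalizers)
  expect_false("red" %in% tab3$colour_class)
  expect_match(attr(tab3, "errors"), "red")
})

test_that("star labels follow the inclusive thresholds and are monotone", {
  expect_equal(p_stars(c(0.00005, 0.0005, 0.005, 0.03, 0.2)),
               c("****", "***", "**", "*", "ns"))
  # inclusive bounds
  expect_equal(p_stars(c(1e-4, 1e-3, 0.01, 0.05, 0.0500001)),
               c("****", "***", "**", "*", "ns"))
  # monotone step function of p
  grid <- sort(stats::runif(200))
  stars <- p_stars(grid)
  rank <- c("****" = 4, "***" = 3, "**" = 2, "*" = 1, ns = 0)[stars]
  expect_true(all(diff(rank) <= 0))
})

test_that("group comparison uses a two-sided rank-sum test", {
  a <- c(1.1, 1.3, 0.9, 1.2, 1.0)
  b <- c(3.1, 2.9, 3.3, 3.0, 3.2)
  res <- compare_groups(a, b)
  expect_equal(res$p_value,
               stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
  expect_true(res$stars %in% c("**", "***", "****"))
  expect_error(compare_groups(numeric(0), b), class = "es_input_error")
})
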