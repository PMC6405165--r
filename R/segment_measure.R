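#' Otsu automatic threshold
#'
#' Computes the intensity threshold maximizing the between-class variance of
#' the image histogram (256 bins over the observed intensity range). Class
#' means are taken from the exact per-bin pixel sums, so the returned
#' threshold maximizes the true between-class variance of the binned
#' partition. Foreground is defined throughout the package as pixels
#' *strictly greater* than the threshold. Ties are broken towards the lowest
#' maximizing threshold.
#'
#' @param image Numeric matrix (or vector) of intensities with at least two
#'   distinct finite values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold intensity (a bin boundary).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  if (any(!is.finite(x))) es_stop("image contains non-finite values", "es_image_error")
  rng <- range(x)
  if (!(rng[2] > rng[1]))
    es_stop("constant image: histogram has no separable classes", "es_degenerate_image")
  width <- rng[2] - rng[1]
  # right-closed bins: bin k holds values in (breaks[k], breaks[k+1]]
  bin <- pmin(pmax(ceiling((x - rng[1]) / width * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(matrix(x, ncol = 1), group = bin)
  sums[as.integer(rownames(rs))] <- rs[, 1]

  n <- length(x)
  total <- sum(sums)
  cc <- cumsum(counts)[-n_bins]
  cs <- cumsum(sums)[-n_bins]
  n0 <- cc
  n1 <- n - cc
  bcv <- rep(-Inf, n_bins - 1L)
  valid <- n0 > 0 & n1 > 0
  mu0 <- cs[valid] / n0[valid]
  mu1 <- (total - cs[valid]) / n1[valid]
  bcv[valid] <- (n0[valid] / n) * (n1[valid] / n) * (mu0 - mu1)^2
  k <- which.max(bcv)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  breaks[k + 1]
}

#' Combined embryo mask from two channels
#'
#' Thresholds each channel with [otsu_threshold()] and intersects the two
#' foregrounds, so a single region — pixels above threshold in *both*
#' channels — is measured in either channel. A constant channel (no
#' separable classes) or an empty intersection yields an all-`FALSE` mask
#' flagged via the `"flag"` attribute rather than an error, feeding the QC
#' stage.
#'
#' @param channel_a,channel_b Intensity matrices of equal dimensions.
#' @return Logical mask matrix; attributes `thresholds` (per-channel Otsu
#'   thresholds, `NA` where degenerate) and, when empty, `flag`.
#' @export
dual_channel_mask <- function(channel_a, channel_b) {
  if (!identical(dim(channel_a), dim(channel_b)))
    es_stop("channel dimensions differ", "es_image_error")
  th <- vapply(list(channel_a, channel_b), function(ch) {
    tryCatch(otsu_threshold(ch), es_degenerate_image = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(th)) {
    mask <- matrix(FALSE, nrow(channel_a), ncol(channel_a))
    attr(mask, "thresholds") <- th
    attr(mask, "flag") <- "degenerate channel"
    return(mask)
  }
  mask <- (channel_a > th[1]) & (channel_b > th[2])
  attr(mask, "thresholds") <- th
  if (!any(mask)) attr(mask, "flag") <- "empty intersection"
  mask
}

#' Intensity statistics within a mask
#'
#' Mean, median, sample standard deviation and pixel count of the masked
#' region. Background pixels are excluded, not subtracted. An empty mask
#' yields an unavailable measurement (`NA` statistics, area 0).
#'
#' @param image Intensity matrix.
#' @param mask Logical mask of the same dimensions.
#' @return One-row data frame with columns `mean`, `median`, `sd`, `area`.
#' @export
measure_masked <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    es_stop("image and mask dimensions differ", "es_image_error")
  if (!any(mask))
    return(data.frame(mean = NA_real_, median = NA_real_, sd = NA_real_, area = 0L))
  vals <- image[mask]
  data.frame(mean = mean(vals), median = stats::median(vals),
             sd = stats::sd(vals), area = length(vals))
}

#' Combine per-slice measurements of one well/channel/timepoint
#'
#' Area-weighted pooling of z-slice statistics: the aggregate mean and
#' sample SD equal exactly those of all masked pixels pooled across slices
#' (reconstructed from per-slice moments); the aggregate median is the
#' area-weighted mean of slice medians (the exact pooled median is not
#' recoverable from slice summaries). Slices with empty masks are ignored;
#' if no slice is valid the timepoint is marked missing.
#'
#' @param per_slice Data frame of slice measurements with columns `mean`,
#'   `median`, `sd`, `area` (one row per z-slice).
#' @return One-row data frame with columns `mean`, `median`, `sd`, `area`.
#' @export
aggregate_z <- function(per_slice) {
  valid <- per_slice$area >= 1 & is.finite(per_slice$mean)
  s <- per_slice[valid, , drop = FALSE]
  if (nrow(s) == 0)
    return(data.frame(mean = NA_real_, median = NA_real_, sd = NA_real_, area = 0L))
  area_total <- sum(s$area)
  mean_agg <- sum(s$mean * s$area) / area_total
  # pooled sum of squares from per-slice moments; sd NA for singleton slices
  ss_within <- ifelse(s$area > 1, s$sd^2 * (s$area - 1), 0)
  ss_total <- sum(ss_within) + sum(s$area * s$mean^2) - area_total * mean_agg^2
  sd_agg <- if (area_total > 1) sqrt(max(ss_total, 0) / (area_total - 1)) else NA_real_
  median_agg <- sum(s$median * s$area) / area_total
  data.frame(mean = mean_agg, median = median_agg, sd = sd_agg,
             area = as.integer(area_total))
}

#' Per-slice measurement of a ratio image stack
#'
#' For each z-slice, divides the test image by the matching control image
#' (pixels with zero or non-finite control excluded), masks the ratio image
#' with [otsu_threshold()] and measures the ratio inside the mask — one
#' measurement per z-slice, the per-slice sampling unit used when comparing
#' fluorophores by light-sheet microscopy. A slice whose control is entirely
#' zero is skipped and reported. A constant ratio image (e.g. a stack
#' divided by itself) cannot be thresholded and is measured over all
#' included pixels instead.
#'
#' @param stack List of test-channel intensity matrices (one per z-slice).
#' @param control_stack Matching list of control-channel matrices.
#' @return Data frame with one row per measured slice: `z` (1-based),
#'   `mean`, `median`, `sd`, `area`, `n_excluded` (control-zero pixels) and
#'   `degenerate` (TRUE where the whole-slice fallback was used). Skipped
#'   slices are reported via the `skipped` attribute.
#' @export
spim_ratio_measure <- function(stack, control_stack) {
  if (length(stack) != length(control_stack))
    es_stop("stacks have different z counts", "es_image_error")
  rows <- list()
  skipped <- integer()
  for (z in seq_along(stack)) {
    test <- stack[[z]]; control <- control_stack[[z]]
    if (!identical(dim(test), dim(control)))
      es_stop("slice dimensions differ between stacks", "es_image_error")
    ok <- is.finite(control) & control != 0 & is.finite(test)
    if (!any(ok)) {
      message(sprintf("slice %d skipped: control entirely zero", z))
      skipped <- c(skipped, z)
      next
    }
    ratio <- test[ok] / control[ok]
    thr <- tryCatch(otsu_threshold(ratio), es_degenerate_image = function(e) NULL)
    degenerate <- is.null(thr)
    vals <- if (degenerate) ratio else ratio[ratio > thr]
    if (length(vals) == 0) { # empty foreground after thresholding
      skipped <- c(skipped, z)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      z = z, mean = mean(vals), median = stats::median(vals),
      sd = stats::sd(vals), area = length(vals),
      n_excluded = sum(!ok), degenerate = degenerate
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(z = integer(), mean = numeric(), median = numeric(),
               sd = numeric(), area = integer(), n_excluded = integer(),
               degenerate = logical())
  attr(out, "skipped") <- skipped
  out
}

#' Quantify every well of a discovered acquisition
#'
#' For each well, timepoint and z-slice, builds the dual-channel Otsu mask
#' from the two fluorescence channels and measures each channel within it,
#' also recording the mean of the pixels outside the mask (the background,
#' used by QC). Rows with `area = 0` mark slices where masking failed.
#'
#' @param index A `series_index` from [discover_series()].
#' @param channels The two fluorescence channels to mask and measure;
#'   defaults to all non-brightfield channels in the index (which must then
#'   number two).
#' @param mask_channel If `NULL` (default), the mask is the dual-channel
#'   intersection. Otherwise the single named channel — conventionally the
#'   injection control, whose expression is condition-independent — supplies
#'   the Otsu mask applied to both channels, which avoids biasing dim test
#'   channels towards their upper noise tail.
#' @return Data frame with columns `well`, `channel`, `t_index`, `time_hpf`,
#'   `z`, `mean`, `median`, `sd`, `area`, `bg_mean`, `bg_area` — the
#'   `measurements.csv` schema.
#' @export
quantify_series <- function(index, channels = NULL, mask_channel = NULL) {
  if (is.null(channels)) channels <- setdiff(unique(index$channel), "bf")
  if (length(channels) != 2)
    es_stop("dual-channel quantification requires exactly two channels", "es_image_error")
  if (!is.null(mask_channel) && !(mask_channel %in% channels))
    es_stop("mask_channel must be one of the quantified channels", "es_image_error")
  idx <- index[index$channel %in% channels, , drop = FALSE]
  rows <- vector("list", 0)
  for (well in unique(idx$well)) {
    w <- idx[idx$well == well, , drop = FALSE]
    for (ti in sort(unique(w$t_index))) {
      wt <- w[w$t_index == ti, , drop = FALSE]
      time_hpf <- wt$time_hpf[1]
      for (z in sort(unique(wt$z))) {
        paths <- vapply(channels, function(ch) {
          p <- wt$path[wt$channel == ch & wt$z == z]
          if (length(p) != 1) NA_character_ else p
        }, character(1))
        if (anyNA(paths)) next  # incomplete channel pair at this slice
        imgs <- lapply(paths, read_image)
        mask <- if (is.null(mask_channel)) {
          dual_channel_mask(imgs[[1]], imgs[[2]])
        } else {
          ref_img <- imgs[[match(mask_channel, channels)]]
          thr <- tryCatch(otsu_threshold(ref_img),
                          es_degenerate_image = function(e) NA_real_)
          if (is.na(thr)) matrix(FALSE, nrow(ref_img), ncol(ref_img))
          else ref_img > thr
        }
        for (ci in seq_along(channels)) {
          m <- measure_masked(imgs[[ci]], mask)
          bg <- imgs[[ci]][!mask]
          rows[[length(rows) + 1]] <- cbind(
            data.frame(well = well, channel = channels[ci], t_index = ti,
                       time_hpf = time_hpf, z = z, stringsAsFactors = FALSE),
            m,
            data.frame(bg_mean = if (length(bg)) mean(bg) else NA_real_,
                       bg_area = length(bg))
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-slice measurements to one value per well/channel/timepoint
#'
#' Applies [aggregate_z()] to the slice measurements of each
#' (well, channel, timepoint); the background mean is pooled analogously,
#' weighted by background pixel counts.
#'
#' @param measurements Output of [quantify_series()].
#' @return Data frame with one row per well/channel/timepoint and columns
#'   `well`, `channel`, `t_index`, `time_hpf`, `mean`, `median`, `sd`,
#'   `area`, `bg_mean`.
#' @export
aggregate_measurements <- function(measurements) {
  key <- interaction(measurements$well, measurements$channel,
                     measurements$t_index, drop = TRUE)
  parts <- split(measurements, key)
  rows <- lapply(parts, function(p) {
    agg <- aggregate_z(p)
    bg_ok <- is.finite(p$bg_mean) & p$bg_area > 0
    bg_mean <- if (any(bg_ok))
      sum(p$bg_mean[bg_ok] * p$bg_area[bg_ok]) / sum(p$bg_area[bg_ok]) else NA_real_
    data.frame(well = p$well[1], channel = p$channel[1], t_index = p$t_index[1],
               time_hpf = p$time_hpf[1], mean = agg$mean, median = agg$median,
               sd = agg$sd, area = agg$area, bg_mean = bg_mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$well, out$channel, out$t_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
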