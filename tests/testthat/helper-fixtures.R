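# Shared fixtures and independent oracles, built in code at test time.

# Usage table with an informative glycine family (GGC 30, GGA 10, GGG 5,
# GGT 5) and flat frequency 1 elsewhere.
toy_glycine_usage <- function() {
  f <- stats::setNames(rep(1, 64), all_codons())
  f[c("GGC", "GGA", "GGG", "GGT")] <- c(30, 10, 5, 5)
  codon_usage_table(f, species = "toy")
}

# Reproducible synthetic usage table with strictly positive random counts.
random_usage_table <- function(seed = 42) {
  codons <- all_codons()
  f <- with_seed(seed, stats::setNames(sample(1:100, 64, replace = TRUE), codons))
  codon_usage_table(f, species = "synthetic")
}

# Exhaustive between-class-variance scan over the 256-bin histogram
# partition, with class statistics computed directly from the raw pixels;
# first maximizing candidate wins, mirroring the documented tie rule.
otsu_scan_oracle <- function(image, n_bins = 256L) {
  x <- as.numeric(image)
  rng <- range(x)
  width <- rng[2] - rng[1]
  bin <- pmin(pmax(ceiling((x - rng[1]) / width * n_bins), 1L), n_bins)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  n <- length(x)
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    bg <- x[bin <= k]
    fg <- x[bin > k]
    if (length(bg) == 0 || length(fg) == 0) next
    v <- (length(bg) / n) * (length(fg) / n) * (mean(bg) - mean(fg))^2
    if (v > best) {
      best <- v
      best_k <- k
    }
  }
  breaks[best_k + 1]
}

# Per-pixel brute-force movement index for one frame pair.
movement_pair_oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (as.numeric(b[[i]]) - as.numeric(a[[i]]))^2
  s / length(a)
}

# Square test image with a centred bright (or dark) disk on a flat
# background, optionally with integer-rounded Gaussian noise.
disk_image <- function(size = 48, radius = 10, fg = 2000, bg = 100,
                       noise_sd = 0, cx = (size + 1) / 2, cy = (size + 1) / 2,
                       seed = NULL) {
  px <- seq_len(size)
  img <- matrix(bg, size, size)
  inside <- outer(px, px, function(y, x) (x - cx)^2 + (y - cy)^2 <= radius^2)
  img[inside] <- fg
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(size * size, 0, noise_sd) else
      with_seed(seed, stats::rnorm(size * size, 0, noise_sd))
    img <- img + matrix(noise, size, size)
  }
  round(pmin(pmax(img, 0), 65535))
}

# Small two-condition fluorescence simulation used by several suites.
small_fluor_sim <- function(dir, seed = 7, dead_well_fraction = 0,
                            ratios = c(a = 2, b = 0.5), n_wells_each = 2,
                            movement = 0) {
  n_cond <- length(ratios)
  layout <- randomize_layout(
    stats::setNames(rep(n_wells_each, n_cond), names(ratios)),
    rows = 2, cols = ceiling(n_cond * n_wells_each / 2), seed = seed
  )
  config <- sim_config(
    plate_rows = 2, plate_cols = ceiling(n_cond * n_wells_each / 2),
    image_size = 64, t_start = 6, t_end = 14, t_step = 120, z_slices = 2,
    channels = c("green", "red"), background_level = 50, noise_sd = 500,
    signal_level = 10000, embryo_radius = 12, injection_volume_cv = 0.3,
    dead_well_fraction = dead_well_fraction, seed = seed + 1
  )
  models <- lapply(names(ratios), function(nm)
    condition_model(nm, brightness = c(green = unname(ratios[[nm]]), red = 1),
                    movement_amplitude = movement))
  sim <- simulate_plate(config, layout, models, dir)
  list(sim = sim, layout = layout, config = config)
}
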