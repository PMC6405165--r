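#' Simulation configuration for a synthetic plate acquisition
#'
#' Bundles the acquisition parameters of a simulated multi-well time-lapse
#' screen. Defaults emulate a typical plate-imager run on fish embryos: a
#' 96-well plate imaged every 20 minutes for 40 hours, two fluorescence
#' channels and 12 z-slices per timepoint, 16-bit grayscale frames.
#'
#' @param plate_rows,plate_cols Plate dimensions.
#' @param image_size Square image side in pixels.
#' @param t_start,t_end Acquisition window in hours post fertilization (hpf).
#' @param t_step Acquisition interval in minutes.
#' @param z_slices Number of z-slices per timepoint (1 for brightfield runs).
#' @param channels Character vector of channel names. A channel named
#'   `"bf"` is rendered as brightfield (embryo darker than background);
#'   all other channels are fluorescence.
#' @param background_level Mean background intensity (camera counts) in
#'   fluorescence channels.
#' @param noise_sd Gaussian read-noise standard deviation (counts), added to
#'   every pixel of every frame.
#' @param signal_level Fluorescence amplitude in counts for a condition of
#'   brightness 1 at injection volume factor 1 (before expression kinetics).
#' @param embryo_radius Embryo disk radius in pixels.
#' @param injection_volume_cv Coefficient of variation of the log-normal
#'   per-well injection volume factor (shared by all channels of a well).
#' @param dead_well_fraction Probability that a loaded well holds a dead or
#'   non-developing embryo (background only in fluorescence channels).
#' @param bf_background,bf_embryo_level Brightfield background and embryo
#'   intensity (counts); the embryo is darker than the background.
#' @param seed Integer seed; identical configurations give bit-identical
#'   simulated plates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(plate_rows = 8L, plate_cols = 12L, image_size = 64L,
                       t_start = 0, t_end = 40, t_step = 20,
                       z_slices = 12L, channels = c("green", "red"),
                       background_level = 100, noise_sd = 500,
                       signal_level = 10000, embryo_radius = 12,
                       injection_volume_cv = 0.3, dead_well_fraction = 0.1,
                       bf_background = 20000, bf_embryo_level = 10000,
                       seed = 1L) {
  config <- list(
    plate_rows = as.integer(plate_rows), plate_cols = as.integer(plate_cols),
    image_size = as.integer(image_size),
    t_start = t_start, t_end = t_end, t_step = t_step,
    z_slices = as.integer(z_slices), channels = as.character(channels),
    background_level = background_level, noise_sd = noise_sd,
    signal_level = signal_level, embryo_radius = embryo_radius,
    injection_volume_cv = injection_volume_cv,
    dead_well_fraction = dead_well_fraction,
    bf_background = bf_background, bf_embryo_level = bf_embryo_level,
    seed = as.integer(seed)
  )
  validate_sim_config(config)
  class(config) <- "sim_config"
  config
}

validate_sim_config <- function(config) {
  with(config, {
    if (!(t_end > t_start)) es_stop("t_end must exceed t_start", "es_config_error")
    if (!(t_step > 0)) es_stop("t_step must be positive", "es_config_error")
    if (!(image_size > 4 * embryo_radius))
      es_stop("image_size must exceed 4 * embryo_radius", "es_config_error")
    if (dead_well_fraction < 0 || dead_well_fraction > 1)
      es_stop("dead_well_fraction must lie in [0, 1]", "es_config_error")
    if (length(channels) < 1) es_stop("at least one channel required", "es_config_error")
    if (noise_sd < 0 || background_level < 0 || signal_level <= 0)
      es_stop("intensity parameters must be non-negative (signal_level positive)",
              "es_config_error")
  })
  invisible(config)
}

#' Acquisition timepoints of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Numeric vector of acquisition times in hpf.
#' @export
sim_times <- function(config) {
  seq(config$t_start, config$t_end, by = config$t_step / 60)
}

#' Kinetic model of a simulated condition
#'
#' Describes one injected construct: per-channel brightness, a two-timescale
#' expression model (maturation rise, slow decay; injected mRNA reporters rise
#' after injection and then fade during development), and the embryo's
#' expected per-frame displacement under the condition's anaesthetic regime.
#'
#' @param name Condition label, matching the plate layout.
#' @param brightness Non-negative relative amplitude; either a single number
#'   applied to all fluorescence channels or a named vector per channel.
#' @param maturation_time Fluorophore maturation timescale in hours.
#' @param decay_time Signal decay timescale in hours.
#' @param movement_amplitude Per-axis standard deviation, in pixels, of the
#'   embryo's per-frame random-walk step (0 = fully anaesthetized).
#' @param is_reference_channel_only If `TRUE`, the condition only expresses in
#'   the reference channel.
#' @return A list of class `condition_model`.
#' @export
condition_model <- function(name, brightness = 1, maturation_time = 2,
                            decay_time = 30, movement_amplitude = 0,
                            is_reference_channel_only = FALSE) {
  if (any(brightness < 0)) es_stop("brightness must be >= 0", "es_config_error")
  if (maturation_time <= 0 || decay_time <= 0)
    es_stop("maturation_time and decay_time must be positive", "es_config_error")
  if (movement_amplitude < 0)
    es_stop("movement_amplitude must be >= 0", "es_config_error")
  structure(list(name = name, brightness = brightness,
                 maturation_time = maturation_time, decay_time = decay_time,
                 movement_amplitude = movement_amplitude,
                 is_reference_channel_only = isTRUE(is_reference_channel_only)),
            class = "condition_model")
}

#' Expression kinetics of an injected reporter
#'
#' Mean relative signal at time `t` hpf for a reporter with maturation
#' timescale `maturation_time` and decay timescale `decay_time`:
#' `(1 - exp(-t / maturation_time)) * exp(-t / decay_time)`, clamped at 0 for
#' negative times. The product of a saturating rise and an exponential fall
#' is the simplest form exposing both an early maturation phase and the slow
#' decrease of injected-mRNA fluorescence over development.
#'
#' @param t Time in hpf (vectorized).
#' @param maturation_time,decay_time Timescales in hours.
#' @return Relative signal in `[0, 1)`.
#' @export
expression_kinetics <- function(t, maturation_time, decay_time) {
  pmax(0, (1 - exp(-pmax(t, 0) / maturation_time)) * exp(-pmax(t, 0) / decay_time))
}

channel_brightness <- function(model, channel, ref_channel) {
  b <- model$brightness
  if (model$is_reference_channel_only && !identical(channel, ref_channel)) return(0)
  if (length(b) == 1 && is.null(names(b))) return(unname(b))
  if (!is.null(names(b)) && channel %in% names(b)) return(unname(b[[channel]]))
  if (length(b) == 1) return(unname(b))
  es_stop(sprintf("condition '%s' has no brightness for channel '%s'",
                  model$name, channel), "es_config_error")
}

# Mild symmetric z-profile so slices differ without changing channel ratios.
z_profile <- function(z, n_z) {
  if (n_z <= 1) return(1)
  mid <- (n_z + 1) / 2
  1 - 0.25 * ((z - mid) / ((n_z - 1) / 2))^2
}

disk_mask <- function(image_size, cx, cy, radius) {
  px <- seq_len(image_size)
  outer(px, px, function(y, x) (x - cx)^2 + (y - cy)^2 <= radius^2)
}

#' Simulate a ground-truthed plate acquisition
#'
#' Renders one 16-bit grayscale TIFF per well/channel/z/timepoint under the
#' acquisition described by `config`, the well-to-condition map in `layout`
#' and the per-condition kinetic models in `models`, writing files named
#' `<WELL>_T<t>_C<channel>_Z<z>.tif` plus `ground_truth.csv` and
#' `acquisition.yaml` into `dir`.
#'
#' Inside the embryo disk, the fluorescence signal follows
#' `v * b * signal_level * kinetics(t) * z_profile(z)` on top of the
#' background, where `v` is the well's log-normal injection volume factor
#' (mean 1, CV `injection_volume_cv`, shared across channels so that channel
#' ratios cancel it) and `b` the condition's per-channel brightness. The
#' embryo centroid performs a clamped 2-D Gaussian random walk with per-axis
#' step SD `movement_amplitude`; steps that would push the disk outside the
#' field of view are clamped and recorded. Dead wells (drawn with probability
#' `dead_well_fraction`) show background only in fluorescence channels and a
#' motionless embryo in brightfield. Empty layout positions produce no files.
#'
#' @param config A [sim_config()].
#' @param layout A `plate_layout` from [randomize_layout()].
#' @param models List of [condition_model()] objects covering every
#'   non-empty condition in `layout`.
#' @param dir Output directory (created if needed).
#' @param ref_channel Reference (injection-control) channel name used to
#'   record the true test/reference brightness ratio; defaults to the last
#'   fluorescence channel.
#' @return Invisibly, a list of class `plate_simulation` with elements
#'   `dir`, `config`, `layout`, `wells` (per-well ground truth: condition,
#'   injection volume factor, true brightness ratio, dead flag) and
#'   `ground_truth` (long table adding the per-timepoint centroid track and
#'   clamp flags; also written to `ground_truth.csv`).
#' @export
simulate_plate <- function(config, layout, models, dir,
                           ref_channel = NULL) {
  validate_sim_config(config)
  if (!inherits(layout, "data.frame")) es_stop("layout must be a data frame", "es_config_error")
  model_names <- vapply(models, function(m) m$name, character(1))
  names(models) <- model_names
  conditions <- setdiff(unique(layout$condition), "empty")
  missing <- setdiff(conditions, model_names)
  if (length(missing) > 0)
    es_stop(paste0("no condition model for: ", paste(missing, collapse = ", ")),
            "es_config_error")
  fluor_channels <- setdiff(config$channels, "bf")
  if (is.null(ref_channel))
    ref_channel <- if (length(fluor_channels) > 0) fluor_channels[length(fluor_channels)] else NA_character_
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  times <- sim_times(config)
  n_t <- length(times)
  size <- config$image_size
  n_px <- size * size
  cv <- config$injection_volume_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2
  margin <- config$embryo_radius + 1

  loaded <- layout[layout$condition != "empty", , drop = FALSE]
  wells_gt <- vector("list", nrow(loaded))
  track_gt <- vector("list", nrow(loaded))

  set.seed(config$seed)
  for (i in seq_len(nrow(loaded))) {
    well <- loaded$well[i]
    cond <- loaded$condition[i]
    model <- models[[cond]]
    v <- stats::rlnorm(1, meanlog = meanlog, sdlog = sdlog)
    is_dead <- stats::runif(1) < config$dead_well_fraction

    # clamped random walk of the embryo centroid, from the image centre
    cx <- numeric(n_t); cy <- numeric(n_t); clamped <- logical(n_t)
    cx[1] <- cy[1] <- (size + 1) / 2
    amp <- if (is_dead) 0 else model$movement_amplitude
    if (n_t > 1) {
      steps <- matrix(stats::rnorm(2 * (n_t - 1), mean = 0, sd = amp), ncol = 2)
      for (ti in 2:n_t) {
        x_raw <- cx[ti - 1] + steps[ti - 1, 1]
        y_raw <- cy[ti - 1] + steps[ti - 1, 2]
        cx[ti] <- min(max(x_raw, margin), size - margin + 1)
        cy[ti] <- min(max(y_raw, margin), size - margin + 1)
        clamped[ti] <- (cx[ti] != x_raw) || (cy[ti] != y_raw)
      }
    }

    ratio <- if (!is.na(ref_channel) && length(fluor_channels) >= 2) {
      test_channel <- fluor_channels[fluor_channels != ref_channel][1]
      b_ref <- channel_brightness(model, ref_channel, ref_channel)
      if (b_ref > 0) channel_brightness(model, test_channel, ref_channel) / b_ref else NA_real_
    } else NA_real_

    for (ti in seq_len(n_t)) {
      disk <- disk_mask(size, cx[ti], cy[ti], config$embryo_radius)
      kin <- expression_kinetics(times[ti], model$maturation_time, model$decay_time)
      for (channel in config$channels) {
        if (identical(channel, "bf")) {
          base <- matrix(config$bf_background, size, size)
          base[disk] <- config$bf_embryo_level
          # brightfield: single autofocus slice, Z index 0
          img <- base + matrix(stats::rnorm(n_px, 0, config$noise_sd), size, size)
          write_image(clamp_counts(img), file.path(dir, frame_filename(well, ti - 1L, channel, 0L)))
        } else {
          b <- channel_brightness(model, channel, ref_channel)
          for (z in seq_len(config$z_slices)) {
            base <- matrix(config$background_level, size, size)
            if (!is_dead && b > 0)
              base[disk] <- base[disk] +
                v * b * config$signal_level * kin * z_profile(z, config$z_slices)
            img <- base + matrix(stats::rnorm(n_px, 0, config$noise_sd), size, size)
            write_image(clamp_counts(img),
                        file.path(dir, frame_filename(well, ti - 1L, channel, z - 1L)))
          }
        }
      }
    }

    wells_gt[[i]] <- data.frame(
      well = well, condition = cond, injection_volume_factor = v,
      true_brightness_ratio = ratio, is_dead = is_dead,
      stringsAsFactors = FALSE
    )
    track_gt[[i]] <- data.frame(
      well = well, condition = cond, t_index = seq_len(n_t) - 1L,
      time_hpf = times, cx = cx, cy = cy, clamped = clamped,
      injection_volume_factor = v, true_brightness_ratio = ratio,
      is_dead = is_dead, stringsAsFactors = FALSE
    )
  }

  wells <- do.call(rbind, wells_gt)
  ground_truth <- do.call(rbind, track_gt)
  write_table_csv(ground_truth, file.path(dir, "ground_truth.csv"))
  yaml::write_yaml(unclass(config), file.path(dir, "acquisition.yaml"))

  invisible(structure(
    list(dir = dir, config = config, layout = layout, times = times,
         wells = wells, ground_truth = ground_truth, ref_channel = ref_channel),
    class = "plate_simulation"
  ))
}

clamp_counts <- function(img) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

frame_filename <- function(well, t_index, channel, z_index) {
  sprintf("%s_T%d_C%s_Z%d.tif", well, t_index, channel, z_index)
}
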