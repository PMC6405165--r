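#' Read or write a grayscale intensity image
#'
#' Images are stored as 8- or 16-bit grayscale TIFF and represented in R as
#' numeric matrices of integer camera counts (0..255 or 0..65535). Reading a
#' written image returns the counts bit-exactly.
#'
#' @param path TIFF file path.
#' @param img Numeric matrix of non-negative integer counts.
#' @param bits Bit depth for writing, 8 or 16.
#' @return `read_image()` returns a numeric matrix of counts.
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]  # tolerate single-plane colour
  storage.mode(img) <- "double"
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) es_stop("bits must be 8 or 16", "es_io_error")
  maxval <- 2^bits - 1
  if (any(img < 0) || any(img > maxval))
    es_stop(sprintf("pixel counts outside [0, %d]", maxval), "es_io_error")
  tiff::writeTIFF(img / maxval, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# Convert a "{well}_T{t}_C{channel}_Z{z}" style template to a capturing regex.
# Returns the regex plus the order of the captured fields.
naming_template_regex <- function(template) {
  placeholders <- c(well = "\\{well\\}", t = "\\{t\\}",
                    channel = "\\{channel\\}", z = "\\{z\\}")
  captures <- c(well = "([A-Za-z][0-9]{1,2})", t = "([0-9]+)",
                channel = "([A-Za-z0-9]+)", z = "([0-9]+)")
  found <- vapply(placeholders, function(p) regexpr(p, template)[1], numeric(1))
  if (any(found < 0))
    es_stop("naming template must contain {well}, {t}, {channel} and {z}", "es_io_error")
  order_fields <- names(sort(found))
  rx <- gsub("([.()\\^$+*?|\\[\\]\\\\])", "\\\\\\1", template, perl = TRUE)
  for (f in names(placeholders)) rx <- sub(placeholders[[f]], captures[[f]], rx)
  list(regex = paste0("^", rx, "\\.tiff?$"), fields = order_fields)
}

#' Discover well image series from a directory of TIFF frames
#'
#' Indexes every TIFF in `directory` whose name matches the naming template
#' (default `"{well}_T{t}_C{channel}_Z{z}"`, the simulator's convention) into
#' one record per frame. Frame times are reconstructed from acquisition
#' indices as `time_origin + t * time_step / 60` hpf, never from file
#' timestamps, so a rediscovered acquisition is bit-reproducible.
#'
#' @param directory Directory containing the frames.
#' @param template Naming template containing the placeholders `{well}`,
#'   `{t}`, `{channel}` and `{z}` (file extension implied).
#' @param time_origin Time of acquisition index 0, in hpf.
#' @param time_step Acquisition interval in minutes.
#' @return A data frame of class `series_index` with columns `well`,
#'   `channel`, `z`, `t_index`, `time_hpf` and `path`, sorted by well,
#'   channel, z and time. Unparseable file names are skipped with a warning
#'   reporting their count; duplicate (well, channel, z, t) combinations are
#'   an error.
#' @export
discover_series <- function(directory, template = "{well}_T{t}_C{channel}_Z{z}",
                            time_origin = 0, time_step = 20) {
  if (!dir.exists(directory)) es_stop("directory does not exist", "es_io_error")
  pattern_spec <- naming_template_regex(template)
  files <- list.files(directory, pattern = "\\.tiff?$", ignore.case = TRUE)
  hit <- grepl(pattern_spec$regex, files)
  if (any(!hit))
    warning(sprintf("skipped %d file(s) not matching the naming template", sum(!hit)))
  files <- files[hit]
  if (length(files) == 0) {
    warning("no image frames discovered")
    idx <- data.frame(well = character(), channel = character(),
                      z = integer(), t_index = integer(),
                      time_hpf = numeric(), path = character(),
                      stringsAsFactors = FALSE)
    class(idx) <- c("series_index", "data.frame")
    return(idx)
  }
  m <- regmatches(files, regexec(pattern_spec$regex, files))
  caps <- do.call(rbind, lapply(m, function(x) x[-1]))
  colnames(caps) <- pattern_spec$fields
  idx <- data.frame(
    well = caps[, "well"],
    channel = caps[, "channel"],
    z = as.integer(caps[, "z"]),
    t_index = as.integer(caps[, "t"]),
    stringsAsFactors = FALSE
  )
  idx$time_hpf <- time_origin + idx$t_index * time_step / 60
  idx$path <- file.path(directory, files)
  key <- paste(idx$well, idx$channel, idx$z, idx$t_index)
  if (anyDuplicated(key))
    es_stop("duplicate (well, channel, z, timepoint) frames discovered", "es_ambiguity_error")
  idx <- idx[order(idx$well, idx$channel, idx$z, idx$t_index), , drop = FALSE]
  rownames(idx) <- NULL
  class(idx) <- c("series_index", "data.frame")
  idx
}

#' Load the ordered frames of one well/channel series
#'
#' @param index A `series_index` from [discover_series()].
#' @param well,channel Series selector.
#' @param z z-slice index (default 0; brightfield series have a single slice).
#' @return A list with `times` (hpf) and `frames` (list of intensity
#'   matrices), ordered by time.
#' @export
load_series <- function(index, well, channel, z = 0L) {
  sel <- index[index$well == well & index$channel == channel & index$z == z, , drop = FALSE]
  if (nrow(sel) == 0)
    es_stop(sprintf("no frames for well %s channel %s z %d", well, channel, z), "es_io_error")
  sel <- sel[order(sel$t_index), , drop = FALSE]
  list(times = sel$time_hpf, frames = lapply(sel$path, read_image))
}

#' Read an acquisition configuration written by the simulator
#'
#' @param path Path to an `acquisition.yaml`.
#' @return The configuration as a `sim_config` list.
#' @export
read_acquisition_config <- function(path) {
  config <- yaml::read_yaml(path)
  config$channels <- as.character(unlist(config$channels))
  do.call(sim_config, config)
}
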