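#' Frame-differencing movement index
#'
#' For each consecutive brightfield frame pair, the index is the mean over
#' pixels of the squared intensity difference
#' `mean((frame[n+1] - frame[n])^2)`, timestamped at frame `n+1`. The mean
#' (rather than the sum) makes the index independent of image size; no
#' registration or background subtraction is applied. An anaesthetized,
#' motionless embryo yields only the camera-noise floor.
#'
#' @param frames List of >= 2 intensity matrices of equal dimensions, in
#'   acquisition order.
#' @param times Acquisition times in hpf, one per frame.
#' @return Data frame of class `movement_trace` with columns `time_hpf`
#'   (time of the later frame of each pair) and `index`; one row per
#'   consecutive pair.
#' @export
movement_index <- function(frames, times) {
  n <- length(frames)
  if (n < 2) es_stop("movement index requires at least 2 frames", "es_input_error")
  if (length(times) != n) es_stop("one time per frame required", "es_input_error")
  dims <- dim(frames[[1]])
  idx <- vapply(seq_len(n - 1), function(i) {
    a <- frames[[i]]; b <- frames[[i + 1]]
    if (!identical(dim(b), dims)) es_stop("frames differ in dimensions", "es_input_error")
    mean((as.numeric(b) - as.numeric(a))^2)
  }, numeric(1))
  out <- data.frame(time_hpf = times[-1], index = idx)
  class(out) <- c("movement_trace", "data.frame")
  out
}

#' Movement traces for every well of a brightfield acquisition
#'
#' @param index A `series_index` from [discover_series()].
#' @param layout A `plate_layout` data frame supplying condition labels.
#' @param channel Brightfield channel name (default `"bf"`).
#' @param z z-slice index of the single autofocus slice (default 0).
#' @return Data frame with columns `well`, `condition`, `time_hpf`, `index`.
#' @export
movement_traces <- function(index, layout, channel = "bf", z = 0L) {
  wells <- intersect(unique(index$well[index$channel == channel]),
                     layout$well[layout$condition != "empty"])
  rows <- lapply(wells, function(well) {
    series <- load_series(index, well, channel, z)
    tr <- movement_index(series$frames, series$times)
    data.frame(well = well,
               condition = layout$condition[match(well, layout$well)],
               time_hpf = tr$time_hpf, index = tr$index,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Align plates by developmental stage
#'
#' Shifts each plate's times by its user-supplied staging offset so that
#' the stated starting stage maps onto the common time origin (the plate
#' with the more advanced starting stage defines time 0). Staging is a
#' manual act; offsets are inputs, not detected. Timepoints outside the
#' post-alignment overlap window are retained but flagged.
#'
#' @param plate_traces Named list of movement-trace data frames (columns
#'   including `time_hpf`).
#' @param stage_offsets Named numeric vector, plate -> offset in hours,
#'   covering every plate.
#' @return One data frame with columns of the inputs plus `plate`,
#'   aligned `time_hpf` and `in_overlap`; the overlap window is attached as
#'   attribute `window`.
#' @export
stage_align <- function(plate_traces, stage_offsets) {
  if (is.null(names(plate_traces)) || any(!nzchar(names(plate_traces))))
    names(plate_traces) <- paste0("plate", seq_along(plate_traces))
  missing <- setdiff(names(plate_traces), names(stage_offsets))
  if (length(missing) > 0)
    es_stop(paste0("missing stage offset for plate(s): ",
                   paste(missing, collapse = ", ")), "es_alignment_error")
  shifted <- lapply(names(plate_traces), function(nm) {
    p <- plate_traces[[nm]]
    p$time_hpf <- p$time_hpf - stage_offsets[[nm]]
    p$plate <- nm
    p
  })
  lo <- max(vapply(shifted, function(p) min(p$time_hpf), numeric(1)))
  hi <- min(vapply(shifted, function(p) max(p$time_hpf), numeric(1)))
  out <- do.call(rbind, shifted)
  out$in_overlap <- out$time_hpf >= lo & out$time_hpf <= hi
  rownames(out) <- NULL
  attr(out, "window") <- c(lo, hi)
  out
}

#' Summarize movement per condition and timepoint
#'
#' Mean, standard deviation and well count of the movement index across the
#' wells of each condition, per timepoint (each plate keeps its native
#' sampling grid). Wells dropped by QC should be excluded beforehand.
#'
#' @param aligned Movement-trace data frame with columns `condition`,
#'   `time_hpf`, `index` (and optionally `well`).
#' @return Data frame with columns `condition`, `time_hpf`, `mean_index`,
#'   `sd_index`, `n_wells`.
#' @export
summarize_movement <- function(aligned) {
  key <- interaction(aligned$condition, aligned$time_hpf, drop = TRUE)
  parts <- split(aligned, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(condition = p$condition[1], time_hpf = p$time_hpf[1],
               mean_index = mean(p$index), sd_index = stats::sd(p$index),
               n_wells = nrow(p), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$condition, out$time_hpf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a startle-response assay
#'
#' Each fish is startled a fixed number of times and its responses counted;
#' groups are summarized and compared pairwise by [compare_groups()]
#' (two-sided rank-sum with star labels).
#'
#' @param response_counts Data frame with columns `fish`, `condition` and
#'   `responses` (responses out of `trials`).
#' @param trials Number of startle trials per fish (default 10).
#' @return List with `summary` (per-condition n, mean, median responses)
#'   and `comparisons` (pairwise `p_value` and `stars`).
#' @export
score_startle <- function(response_counts, trials = 10L) {
  req <- c("fish", "condition", "responses")
  if (!all(req %in% names(response_counts)))
    es_stop("response_counts needs columns fish, condition, responses", "es_input_error")
  r <- response_counts$responses
  if (any(r < 0 | r > trials))
    es_stop(sprintf("response counts must lie in [0, %d]", trials), "es_input_error")
  parts <- split(r, response_counts$condition)
  summary <- data.frame(
    condition = names(parts),
    n_fish = vapply(parts, length, integer(1)),
    mean_responses = vapply(parts, mean, numeric(1)),
    median_responses = vapply(parts, stats::median, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  groups <- names(parts)
  comparisons <- list()
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      cg <- compare_groups(parts[[pairs[1, j]]], parts[[pairs[2, j]]])
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 p_value = cg$p_value, stars = cg$stars,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, comparisons = comparisons)
}
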