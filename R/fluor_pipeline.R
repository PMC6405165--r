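#' QC parameters for well filtering
#'
#' @param min_area Minimum embryo mask area (pixels) at each checkpoint.
#' @param min_signal_ratio Minimum ratio of masked mean to background mean
#'   (pixels outside the mask) at each checkpoint; must exceed 1.
#' @param checkpoints Fractional positions along the series at which wells
#'   are checked, in (0, 1]. The defaults `c(1, 0.5)` check the final
#'   ("maximum") timepoint and the series midpoint.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_area = 20, min_signal_ratio = 2, checkpoints = c(1, 0.5)) {
  if (min_signal_ratio <= 1) es_stop("min_signal_ratio must exceed 1", "es_config_error")
  if (any(checkpoints <= 0 | checkpoints > 1))
    es_stop("checkpoints must lie in (0, 1]", "es_config_error")
  structure(list(min_area = min_area, min_signal_ratio = min_signal_ratio,
                 checkpoints = checkpoints), class = "qc_params")
}

#' Drop dead or non-developing wells
#'
#' A well is kept iff, at every checkpoint timepoint (by default the final
#' timepoint and the series midpoint), the embryo mask of the checked
#' channel has area at least `min_area` and its masked mean is at least
#' `min_signal_ratio` times the background mean. Dropped wells carry
#' machine-readable reasons; filtering is total (never errors).
#'
#' @param aggregated Per-timepoint measurements from
#'   [aggregate_measurements()].
#' @param params A [qc_params()] object.
#' @param channel Channel checked for fluorescence (conventionally the
#'   injection-control/reference channel).
#' @return List with `kept` (character vector of wells) and `dropped`
#'   (data frame with columns `well`, `reason`).
#' @export
qc_filter <- function(aggregated, params = qc_params(), channel) {
  agg <- aggregated[aggregated$channel == channel, , drop = FALSE]
  kept <- character()
  dropped <- list()
  for (well in unique(agg$well)) {
    w <- agg[agg$well == well, , drop = FALSE]
    w <- w[order(w$t_index), , drop = FALSE]
    n <- nrow(w)
    reasons <- character()
    for (q in params$checkpoints) {
      i <- max(1L, round(q * n))
      if (!is.finite(w$mean[i]) || w$area[i] < params$min_area) {
        reasons <- c(reasons, sprintf("no mask at checkpoint %.2f", q))
      } else if (!is.finite(w$bg_mean[i]) ||
                 w$mean[i] < params$min_signal_ratio * w$bg_mean[i]) {
        reasons <- c(reasons, sprintf("no signal at checkpoint %.2f", q))
      }
    }
    if (length(reasons) == 0) {
      kept <- c(kept, well)
    } else {
      dropped[[length(dropped) + 1]] <-
        data.frame(well = well, reason = paste(unique(reasons), collapse = "; "),
                   stringsAsFactors = FALSE)
    }
  }
  list(kept = kept,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(well = character(), reason = character()))
}

#' Normalize a test trace by the reference channel at one timepoint
#'
#' Ratiometric injection-volume normalization: every value of the test
#' trace is divided by the reference channel's value at the acquired
#' timepoint nearest `t_norm` (no interpolation). Because co-injected mRNAs
#' share the well's injection volume, the division cancels it.
#'
#' @param test,reference Data frames with columns `time_hpf` and `value`,
#'   both from the same well.
#' @param t_norm Normalization time in hpf (default 10).
#' @return The test data frame with normalized `value`; attributes
#'   `normalization_time` (the actual timepoint used) and `reference_value`.
#'   A missing or non-positive reference value raises an error of class
#'   `es_negative_well` (the well is to be flagged and excluded).
#' @export
normalize_trace <- function(test, reference, t_norm = 10) {
  if (nrow(reference) == 0) es_stop("empty reference trace", "es_negative_well")
  i <- nearest_time_index(reference$time_hpf, t_norm)
  ref_value <- reference$value[i]
  if (!is.finite(ref_value) || ref_value <= 0)
    es_stop("reference value missing or non-positive at normalization time",
            "es_negative_well")
  out <- test
  out$value <- test$value / ref_value
  attr(out, "normalization_time") <- reference$time_hpf[i]
  attr(out, "reference_value") <- ref_value
  out
}

#' Build normalized per-well intensity traces
#'
#' Converts aggregated measurements into per-well test-channel traces
#' normalized to the reference channel at `t_norm` and joins the plate
#' layout's condition labels. Wells whose reference value is missing or
#' non-positive at the normalization timepoint are flagged and excluded.
#'
#' @param aggregated Output of [aggregate_measurements()].
#' @param layout A `plate_layout` data frame.
#' @param test_channel,ref_channel Channel names.
#' @param t_norm Normalization time in hpf.
#' @param wells Optional character vector restricting to QC-kept wells.
#' @return List with `traces` (data frame: `well`, `condition`, `channel`,
#'   `time_hpf`, `value`, `normalized`, `normalization_time`) and `flagged`
#'   (data frame of excluded wells with reasons).
#' @export
build_traces <- function(aggregated, layout, test_channel, ref_channel,
                         t_norm = 10, wells = NULL) {
  if (is.null(wells)) wells <- unique(aggregated$well)
  wells <- intersect(wells, layout$well[layout$condition != "empty"])
  traces <- list(); flagged <- list()
  for (well in wells) {
    test <- aggregated[aggregated$well == well & aggregated$channel == test_channel, ]
    ref <- aggregated[aggregated$well == well & aggregated$channel == ref_channel, ]
    if (nrow(test) == 0) next
    test_tr <- data.frame(time_hpf = test$time_hpf, value = test$mean)
    ref_tr <- data.frame(time_hpf = ref$time_hpf, value = ref$mean)
    norm <- tryCatch(normalize_trace(test_tr, ref_tr, t_norm),
                     es_negative_well = function(e) e)
    if (inherits(norm, "error")) {
      flagged[[length(flagged) + 1]] <-
        data.frame(well = well, reason = conditionMessage(norm),
                   stringsAsFactors = FALSE)
      next
    }
    traces[[length(traces) + 1]] <- data.frame(
      well = well,
      condition = layout$condition[match(well, layout$well)],
      channel = test_channel,
      time_hpf = norm$time_hpf,
      value = norm$value,
      normalized = TRUE,
      normalization_time = attr(norm, "normalization_time"),
      stringsAsFactors = FALSE
    )
  }
  list(traces = if (length(traces)) do.call(rbind, traces) else
         data.frame(well = character(), condition = character(),
                    channel = character(), time_hpf = numeric(),
                    value = numeric(), normalized = logical(),
                    normalization_time = numeric()),
       flagged = if (length(flagged)) do.call(rbind, flagged) else
         data.frame(well = character(), reason = character()))
}

#' Fuse plates onto one comparable intensity axis
#'
#' Rescales every plate to the first (reference) plate using the internal
#' control condition present on all plates: plate `p` is multiplied by
#' `s_p = mean(reference plate's control values over the common time
#' window) / mean(plate p's control values over the same window)`, after
#' which the control curves coincide in the window. Using the window mean
#' rather than a single frame makes the factor robust to single-frame noise
#' and reduces to a per-timepoint ratio when curves are proportional.
#'
#' @param plates Named list of trace data frames (columns `condition`,
#'   `time_hpf`, `value`, ...), one per plate; the first is the reference.
#' @param control_condition Label of the internal control condition.
#' @return A single data frame with a `plate` column and rescaled `value`;
#'   the named scale factors are attached as attribute `scale_factors`.
#' @export
fuse_plates <- function(plates, control_condition) {
  if (length(plates) == 0) es_stop("no plates to fuse", "es_fusion_error")
  if (is.null(names(plates)) || any(!nzchar(names(plates))))
    names(plates) <- paste0("plate", seq_along(plates))
  lo <- max(vapply(plates, function(p) min(p$time_hpf), numeric(1)))
  hi <- min(vapply(plates, function(p) max(p$time_hpf), numeric(1)))
  if (lo > hi) es_stop("plates share no overlapping time window", "es_fusion_error")
  control_mean <- vapply(names(plates), function(nm) {
    p <- plates[[nm]]
    v <- p$value[p$condition == control_condition &
                   p$time_hpf >= lo & p$time_hpf <= hi]
    if (length(v) == 0)
      es_stop(sprintf("plate '%s' has no control condition '%s' in the window",
                      nm, control_condition), "es_fusion_error")
    mean(v)
  }, numeric(1))
  s <- control_mean[1] / control_mean
  fused <- do.call(rbind, lapply(names(plates), function(nm) {
    p <- plates[[nm]]
    p$value <- p$value * s[[nm]]
    p$plate <- nm
    p
  }))
  rownames(fused) <- NULL
  attr(fused, "scale_factors") <- s
  attr(fused, "window") <- c(lo, hi)
  fused
}

#' Rank conditions by normalized intensity at a timepoint
#'
#' For each well, takes the trace value at the acquired timepoint nearest
#' `t`; conditions are summarized across wells and sorted by descending
#' mean, ties broken by condition label (alphabetical).
#'
#' @param traces Trace data frame (columns `well`, `condition`, `time_hpf`,
#'   `value`).
#' @param t Ranking time in hpf (default 10).
#' @return Data frame ordered by rank with columns `condition`, `mean`,
#'   `sd`, `n_wells`.
#' @export
rank_conditions <- function(traces, t = 10) {
  per_well <- lapply(split(traces, traces$well), function(w) {
    i <- nearest_time_index(w$time_hpf, t)
    data.frame(condition = w$condition[1], value = w$value[i],
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, per_well)
  parts <- split(pw$value, pw$condition)
  out <- data.frame(
    condition = names(parts),
    mean = vapply(parts, mean, numeric(1)),
    sd = vapply(parts, stats::sd, numeric(1)),
    n_wells = vapply(parts, length, integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$mean, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean normalized intensity per condition over a time window
#'
#' Includes all timepoints `t` with `from <= t <= to` (default 23-30 hpf).
#'
#' @param traces Trace data frame.
#' @param from,to Window bounds in hpf.
#' @return Named numeric vector of per-condition window means.
#' @export
condition_window_means <- function(traces, from = 23, to = 30) {
  sel <- traces[traces$time_hpf >= from & traces$time_hpf <= to, , drop = FALSE]
  if (nrow(sel) == 0) es_stop("no timepoints inside the window", "es_input_error")
  vapply(split(sel$value, sel$condition), mean, numeric(1))
}

#' Cross-species intensity comparison table
#'
#' Rescales in-vivo window means onto an external reference scale per
#' colour class: within each class, all window means are multiplied by the
#' factor that maps the class's normalizer condition exactly onto its
#' external reference value (e.g. the yellow-class normalizer onto its
#' published value of 1.2). A class whose normalizer is missing or has a
#' non-positive window mean is excluded with an error record.
#'
#' @param window_means Named numeric vector, condition -> internal window
#'   mean (from [condition_window_means()]).
#' @param reference_values Named numeric vector, condition -> external
#'   reference intensity.
#' @param colour_class Named character vector, condition -> colour class
#'   (e.g. `"green"`, `"red"`, `"yellow"`).
#' @param class_normalizers Named character vector, colour class ->
#'   normalizer condition.
#' @return Data frame with columns `condition`, `colour_class`,
#'   `window_mean`, `normalized_internal`, `reference_value`; excluded
#'   classes are reported in attribute `errors`.
#' @export
cross_species_table <- function(window_means, reference_values, colour_class,
                                class_normalizers) {
  conditions <- names(window_means)
  rows <- list(); errors <- character()
  for (cls in names(class_normalizers)) {
    norm_cond <- class_normalizers[[cls]]
    members <- conditions[colour_class[conditions] == cls]
    members <- members[!is.na(members)]
    if (!(norm_cond %in% members) || !is.finite(window_means[[norm_cond]]) ||
        window_means[[norm_cond]] <= 0 || !(norm_cond %in% names(reference_values))) {
      errors <- c(errors, sprintf(
        "class '%s': normalizer '%s' missing or non-positive", cls, norm_cond))
      next
    }
    scale <- reference_values[[norm_cond]] / window_means[[norm_cond]]
    rows[[length(rows) + 1]] <- data.frame(
      condition = members,
      colour_class = cls,
      window_mean = unname(window_means[members]),
      normalized_internal = unname(window_means[members] * scale),
      reference_value = unname(reference_values[members]),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), colour_class = character(),
               window_mean = numeric(), normalized_internal = numeric(),
               reference_value = numeric())
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Two-group comparison with significance stars
#'
#' Two-sided Wilcoxon rank-sum comparison of two samples, with the star
#' label derived from the p value by the conventional inclusive thresholds
#' `**** p <= 1e-4`, `*** p <= 1e-3`, `** p <= 0.01`, `* p <= 0.05`,
#' `ns p > 0.05`.
#'
#' @param values_a,values_b Non-empty numeric samples.
#' @return List with `p_value` and `stars`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    es_stop("both samples must be non-empty", "es_input_error")
  p <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided")$p.value)
  # fully tied samples leave the rank-sum statistic without variance;
  # identical distributions carry no evidence of a difference
  if (!is.finite(p)) p <- 1
  list(p_value = p, stars = p_stars(p))
}

#' Significance star label for a p value
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}
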