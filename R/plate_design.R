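#' Create a randomized multi-well plate layout
#'
#' Assigns experimental conditions to wells of a `rows` x `cols` plate by a
#' uniform random permutation, reproducing the randomized loading schemes used
#' to avoid position effects in plate-based embryo screens. Wells beyond the
#' requested replicate totals are explicitly labelled `"empty"` so that
#' downstream joins can distinguish an intentionally empty well from a missing
#' image file.
#'
#' @param requests Named integer vector mapping condition labels to requested
#'   replicate counts. The sum must not exceed `rows * cols`.
#' @param rows,cols Plate dimensions (default 8 x 12, a 96-well plate).
#' @param seed Integer seed; identical seeds give identical layouts.
#' @return A data frame of class `plate_layout` with columns `well` (e.g.
#'   `"A1"`), `row`, `col` and `condition` (a requested label or `"empty"`),
#'   one row per well in row-major order, with the seed stored as an
#'   attribute.
#' @examples
#' randomize_layout(c(eGFP = 48, mCherry = 48), seed = 1)
#' @export
randomize_layout <- function(requests, rows = 8L, cols = 12L, seed = 1L) {
  if (length(requests) == 0 || is.null(names(requests)) || any(!nzchar(names(requests))))
    es_stop("`requests` must be a named vector of replicate counts", "es_layout_error")
  requests <- vapply(requests, as.integer, integer(1))
  if (any(requests < 0))
    es_stop("replicate counts must be non-negative", "es_layout_error")
  if ("empty" %in% names(requests))
    es_stop("'empty' is a reserved condition label", "es_layout_error")
  n_wells <- rows * cols
  if (sum(requests) > n_wells)
    es_stop(sprintf("requested %d wells but plate holds only %d",
                    sum(requests), n_wells), "es_capacity_error")

  wells <- well_names(rows, cols)
  labels <- c(rep(names(requests), times = requests),
              rep("empty", n_wells - sum(requests)))
  assignment <- with_seed(seed, sample(labels, n_wells, replace = FALSE))

  layout <- data.frame(
    well = wells,
    row = rep(LETTERS[seq_len(rows)], each = cols),
    col = rep(seq_len(cols), times = rows),
    condition = assignment,
    stringsAsFactors = FALSE
  )
  attr(layout, "seed") <- as.integer(seed)
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

# Row-major A1-style well names: A1..A12, B1..B12, ...
well_names <- function(rows, cols) {
  paste0(rep(LETTERS[seq_len(rows)], each = cols), rep(seq_len(cols), times = rows))
}

#' Write or read a plate layout table
#'
#' @param layout A `plate_layout` data frame from [randomize_layout()].
#' @param path Path to a `layout.csv` with columns well, row, col, condition.
#' @return `read_layout()` returns a `plate_layout` data frame.
#' @export
write_layout <- function(layout, path) {
  write_table_csv(as.data.frame(layout), path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well", "row", "col", "condition")
  if (!all(needed %in% names(layout)))
    es_stop("layout file must have columns well, row, col, condition", "es_layout_error")
  class(layout) <- c("plate_layout", "data.frame")
  layout
}
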