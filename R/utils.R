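`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so that seeded helpers do not perturb
#' surrounding simulations.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Index of the acquired timepoint nearest t (first wins on ties, i.e. the
# earlier frame); no interpolation anywhere in the pipeline.
nearest_time_index <- function(times, t) {
  which.min(abs(times - t))
}

es_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "embryoscreen_error")))
}

# Consistent numeric formatting for CSV round trips.
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
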