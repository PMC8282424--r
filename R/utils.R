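# Internal helpers shared across modules.

#' Derive a child seed from a parent seed and a label
#'
#' All stages of the pipeline draw their randomness from one user-facing seed.
#' Child seeds are derived deterministically so that changing the stage label
#' decorrelates streams while keeping the whole run reproducible. Kept below
#' 2^31 so the result is always a valid R integer.
#'
#' @param seed parent integer seed
#' @param label character tag naming the consumer
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

# md5 of an in-memory object via its canonical JSON serialization; used for
# pipeline cache keys (no binary serialization so keys are stable across
# R versions).
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE), f)
  unname(tools::md5sum(f))
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  paste(unname(h), collapse = "+")
}
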