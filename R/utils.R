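# Internal helpers shared across modules.

#' Integer mode with a deterministic tie rule
#'
#' Rounds to the nearest integer, tabulates, and returns the most frequent
#' value; ties are broken towards the smaller value.
#'
#' @param x numeric vector.
#' @return integer scalar.
#' @noRd
int_mode <- function(x) {
  stopifnot(length(x) >= 1)
  v <- as.integer(round(x))
  tab <- table(v)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap FNV-1a style hash of an R object, for provenance blocks.
#' @noRd
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1) || anyNA(x)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x != round(x)) {
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}
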