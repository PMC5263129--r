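#' Derive a child seed from a master seed
#'
#' All stochastic stages in the package draw their seeds through this mixer so
#' that one master seed makes the whole pipeline reproducible while individual
#' stages (simulation, each forest of an ensemble, each RFE cycle) can be
#' re-run in isolation. A multiplicative-congruential hash over the integer
#' key keeps the result in the 32-bit range R requires of `set.seed()`.
#'
#' @param master integer master seed.
#' @param ... further integer key components (stage ids, forest indices, ...).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- c(master, ...)
  stopifnot(length(key) >= 1, all(is.finite(key)))
  h <- 0
  for (v in as.numeric(key)) {
    h <- (h * 69069 + abs(v) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with the calling function's name stripped of namespace noise
abort <- function(...) stop(..., call. = FALSE)

as_count <- function(x, what) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x != round(x)) {
    abort(what, " must be a single non-negative integer")
  }
  as.integer(x)
}
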