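# Internal helpers: classed conditions and deterministic seed derivation.

#' @noRd
gr_abort <- function(message, class, data = NULL, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "goitrisk_error", "error", "condition"),
    list(message = message, call = call, data = data)
  )
  stop(cond)
}

#' Deterministic child seed
#'
#' Derives a reproducible child seed from a root seed and one or two stream
#' indices, so that per-(age group, component) random streams do not depend
#' on evaluation order. Kept within the 32-bit signed integer range.
#' @noRd
gr_child_seed <- function(seed, i, j = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 7919 * as.numeric(i) + 104729 * as.numeric(j)
  as.integer(s %% m)
}

# Polynomial rolling hash (mod 2^31-1) of a character vector; used for run
# manifests only (content fingerprinting, not cryptography).
#' @noRd
gr_content_hash <- function(x) {
  bytes <- as.numeric(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
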