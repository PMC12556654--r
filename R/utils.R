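`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive an independent RNG stream from a base seed and a stream name
#'
#' Each stochastic routine in the package draws from its own stream so that
#' adding or reordering generators never shifts another generator's output.
#' The stream seed is a deterministic 31-bit hash of `(seed, name)`.
#'
#' @param seed Integer base seed.
#' @param name Character stream label (usually the generator name).
#' @return An integer seed below 2^31.
#' @keywords internal
derive_stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# run code under a named RNG stream without disturbing the global RNG
with_stream <- function(seed, name, code) {
  withr::with_seed(derive_stream_seed(seed, name), code)
}

# standardise a product map to the six canonical products (missing -> 0)
canonical_products <- function(x) {
  out <- stats::setNames(numeric(length(fermentation_products)),
                         fermentation_products)
  if (length(x)) {
    x <- x[names(x) %in% fermentation_products]
    out[names(x)] <- unname(x)
  }
  out
}

abort_if <- function(cond, msg, class) {
  if (cond) stop(errorCondition(msg, class = c(class, "gutharvest_error")))
  invisible(NULL)
}

# safe lookup into a named sd vector/list: missing keys count as 0
sd_lookup <- function(sds, key) {
  if (is.null(sds) || !key %in% names(sds)) 0 else unname(sds[[key]])
}
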