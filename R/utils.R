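## Internal helpers: seed derivation, local extrema, small checks.

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' All randomness in the package flows from one master seed; stage- and
#' trial-level seeds are derived with a small string hash so that the result
#' for one trial does not depend on the order in which other trials are
#' generated. Result is always a non-negative integer below 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param ... Key components (coerced to character).
#' @return Integer scalar.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

## strict interior local maxima / minima (plateaus are not extrema)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] > x[i + 1L]]
}

local_minima <- function(x) local_maxima(-x)

## population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
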