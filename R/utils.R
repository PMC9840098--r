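# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL runs the code under the ambient RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up, matching how the reported percentage
#' tables are printed (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties rounded up.
#' @export
round_half_up <- function(x, digits = 2) {
  scaled <- round(x * 10^digits, 9)  # shave binary representation noise
  floor(scaled + 0.5) / 10^digits
}

# integer (< 2^31) to lowercase hex
int_to_hex <- function(x) sprintf("%x", as.integer(x))

# hex string of arbitrary length to double; caller must keep values < 2^53
hex_to_double <- function(x) {
  n <- nchar(x)
  stopifnot(all(n <= 13))
  lo_n <- pmin(n, 6L)
  hi <- substr(x, 1L, n - lo_n)
  lo <- substr(x, n - lo_n + 1L, n)
  hi_v <- ifelse(nchar(hi) > 0, strtoi(hi, 16L), 0L)
  hi_v * 16^lo_n + strtoi(lo, 16L)
}

# halve an even hex integer (used for q = (p - 1) / 2)
halve_hex <- function(x) {
  digits <- strtoi(strsplit(x, "")[[1]], 16L)
  out <- integer(length(digits))
  carry <- 0L
  for (i in seq_along(digits)) {
    v <- carry * 16L + digits[i]
    out[i] <- v %/% 2L
    carry <- v %% 2L
  }
  if (carry != 0L) stop("halve_hex: odd input")
  hex <- paste(sprintf("%x", out), collapse = "")
  hex <- sub("^0+(?=.)", "", hex, perl = TRUE)
  hex
}

# n random bytes as a lowercase hex string, from the ambient (seedable) RNG
rng_hex <- function(n_bytes) {
  paste(sprintf("%02x", sample.int(256L, n_bytes, replace = TRUE) - 1L),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
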