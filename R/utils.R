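## Internal helpers shared across modules.

#' Derive a per-task RNG seed from a master seed
#'
#' Counter-based derivation so that trials drawn from one master seed are
#' mutually independent and individually reproducible under partial re-runs.
#' The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param index nonnegative integer counter (trial number, condition index...).
#' @return an integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  ## multiplicative hash mod the Mersenne prime 2^31 - 1; exact in doubles
  ## because all intermediates stay below 2^53
  m <- (abs(as.numeric(master)) %% 2147483647) + 1
  h <- (m * 48271) %% 2147483647
  h <- (h + (as.numeric(index) + 1) * 69621) %% 2147483647
  h <- (h * 16807) %% 2147483647
  as.integer(h)
}

## Evaluate `code` under `seed` without clobbering the caller's RNG stream.
## seed = NULL leaves the current stream untouched (and advances it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Grid index helpers. Grid positions are 1..extent per axis; the arcmin
## origin sits on the central index ((extent + 1) %/% 2 for odd extents).
grid_center_index <- function(extent) (as.integer(extent) + 1L) %/% 2L

wrap_index <- function(i, extent) ((as.integer(i) - 1L) %% as.integer(extent)) + 1L

## Map arcmin coordinates of diffusion positions (integer multiples of the
## grid spacing, possibly unwrapped) onto cyclic grid indices.
arcmin_to_index <- function(x, spacing, extent) {
  wrap_index(as.integer(round(x / spacing)) + grid_center_index(extent), extent)
}

index_to_arcmin <- function(i, spacing, extent) {
  (as.integer(i) - grid_center_index(extent)) * spacing
}

## Binomial standard error of a fraction-correct estimate.
binomial_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / pmax(n, 1))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
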