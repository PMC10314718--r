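#' Derive a per-stream random seed from a master seed
#'
#' Deterministically maps a master seed and a stream index (for example an
#' image index within an ensemble) to a new seed.  The mapping is a fixed
#' integer hash, stable across platforms and package versions, so an
#' ensemble is a pure function of `(config, n, seed)` and any single image
#' of it can be regenerated in isolation.
#'
#' All arithmetic is carried out in doubles below 2^53, so no integer
#' overflow occurs; the result is always in `[0, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index (vectorised).
#' @return integer vector of derived seeds, same length as `index`.
#' @examples
#' derive_stream_seed(42, 1:3)
#' @export
derive_stream_seed <- function(master, index) {
  if (length(master) != 1L || is.na(master)) {
    stop("'master' must be a single non-missing integer seed")
  }
  if (any(index < 0)) stop("'index' must be nonnegative")
  m <- as.double(master) %% 2147483647
  # Knuth-style multiplicative hash; constants fixed for reproducibility
  s <- (m * 48271 + as.double(index) * 2654435761 + 11) %% 2147483629
  as.integer(s)
}

# run a block with a local RNG state so samplers do not disturb the
# caller's random stream
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) {
    stop("a seed is required: all sampling must be reproducible")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
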