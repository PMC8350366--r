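# Seed plumbing: all randomness in the package flows from one integer
# seed, split into named substreams so that e.g. phantom generation and
# weight initialisation are independently reproducible.

#' Derive a substream seed from a master seed and a stream name
#'
#' Deterministic hash of `(seed, name)` into `[0, 2^31 - 2]`, so that the
#' named sources of randomness (phantom, split, init, augment, ...) are
#' decoupled while remaining fully reproducible from one master seed.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-to-even, the grid-size rounding rule used by the resampler
round_even <- function(x) round(x)
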