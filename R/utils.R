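#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Every stochastic component of a run receives its own seed derived from a
#' single master seed and a short text label (e.g. `"ga"`, `"split"`,
#' `"row37"`). The derivation is a 31-bit multiplicative string hash folded
#' with the master seed, so one integer reproduces an entire pipeline while
#' distinct components get effectively independent streams.
#'
#' @param seed Master seed (single integer).
#' @param label Character label naming the consumer.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "ga") != derive_seed(42, "split")
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
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
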