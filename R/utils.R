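# internal helpers: seeded evaluation without touching global RNG state,
# and deterministic per-stratum seed derivation.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# position-weighted string hash, kept well inside 32-bit integer range;
# vectorized so hashing whole-stratum content strings stays cheap
hash_label <- function(label) {
  bytes <- as.integer(charToRaw(as.character(label)))
  if (length(bytes) == 0L) return(0L)
  w <- (seq_along(bytes) %% 97L) + 1L
  as.integer(sum((bytes * w) %% 1000003) %% 1000003)
}

#' Derive a reproducible seed from a master seed and a key string
#'
#' Seeds are `(master + hash(key)) mod (2^31 - 1)`. The pipeline keys each
#' stratum by its own data content, so a stratum's split seed depends only on
#' that stratum's rows and the master seed: adding, removing or relabelling
#' other strata never changes it, and two strata holding identical data get
#' identical splits.
#'
#' @param master_seed integer master seed for the whole run.
#' @param key key string (coerced to character).
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, key) {
  as.integer((as.numeric(master_seed) + hash_label(key)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
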