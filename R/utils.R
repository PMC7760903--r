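# Internal helpers: seeded RNG streams and small shared utilities.

#' Derive a reproducible RNG stream seed from a base seed and a descriptor
#'
#' Hashes an arbitrary list of descriptor strings/numbers into a 31-bit
#' integer seed, so that every randomised step of the pipeline draws from its
#' own stream identified by *what* it computes (species, GOR pair, animal)
#' rather than by iteration order. Identical base seed and descriptor always
#' give the identical stream.
#'
#' @param seed base integer seed.
#' @param ... descriptor components (coerced to character).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1, "global", "horse", "Rump", "Neck")
stream_seed <- function(seed, ...) {
  parts <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  codes <- utf8ToInt(parts)
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (cc in codes) {
    # 31-bit polynomial rolling hash; kept in double precision (exact < 2^53)
    h <- (h * 31 + cc) %% m
  }
  as.integer(h)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
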