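# internal helpers

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
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
  force(expr)
}

# Derive a stream seed from a master seed; kept well inside 32-bit range.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 7L + 13L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pc <- function(...) stop(..., call. = FALSE)
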