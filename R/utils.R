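# Internal helpers: classed conditions and seed hygiene.

stop_cd <- function(subclass, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("cdtransfer_", subclass), "cdtransfer_error",
              "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

warn_cd <- function(subclass, message) {
  cond <- structure(
    class = c(paste0("cdtransfer_", subclass), "cdtransfer_warning",
              "warning", "condition"),
    list(message = message, call = sys.call(-1))
  )
  warning(cond)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Deterministic per-purpose sub-seeds derived from one master seed. Streams
# are indexed by a fixed registry so adding a draw does not shift the others.
sub_seeds <- function(seed, n_streams = 32L) {
  with_seed(seed, sample.int(2147483646L, n_streams))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
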