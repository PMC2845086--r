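#' @keywords internal
"_PACKAGE"

# Run code under a local RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stream seed derived from a root seed and a string label.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, label, index = 0L) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * (seq_along(utf8ToInt(as.character(label))) %% 97L + 1L))
  as.integer((as.numeric(seed) * 48271 + h * 131 + index * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
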