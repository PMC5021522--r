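# internal helpers

# Set the RNG seed, returning a function that restores the previous state.
# Used where an operation accepts an optional `seed` without disturbing the
# caller's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

# Derive a child seed (31-bit, positive) from a master seed and an index.
# Linear congruential mixing; deterministic and collision-poor enough for
# per-cycle substreams.
child_seed <- function(seed, index) {
  m <- 2147483647
  x <- (as.double(seed %% m) * 48271 + as.double(index) * 16807 + 12345) %% m
  as.integer(x %/% 1 + 1)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
}
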