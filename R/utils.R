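# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Nearest integer with ties rounded toward -Inf (0.5 -> 0, 1.5 -> 1).
# Used to map millisecond onsets to samples on the analysis grid.
nearestSampleTiesDown <- function(x) ceiling(x - 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
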