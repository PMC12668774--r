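# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific 31-bit seed from a global seed and a stage label, so
# that one CLI seed governs all stages without hidden coupling between them.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((as.integer(seed) %% 1000003L) * 131L + h) %% .Machine$integer.max
}

# Mirror the strict upper triangle onto the lower one.
mirror_upper <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

symmetrize <- function(m) (m + t(m)) / 2

# abs-distance matrix |i - j| for an n x n grid (0-based distances)
distance_matrix <- function(n) {
  idx <- seq_len(n)
  abs(outer(idx, idx, "-"))
}
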