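# Internal helpers shared across the package.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# session RNG. A NULL seed runs `code` against the current RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seeds derived from one root seed, so that e.g.
# bootstrap and permutation draws stay stable when other components toggle.
# Kept well below 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  offsets <- c(
    simulation = 101L, bootstrap = 211L, permutation = 307L,
    tissue = 401L, dataset = 503L
  )
  off <- offsets[[stream]]
  # double arithmetic: exact far beyond the 32-bit range, result folded back
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483587)
}

# The stage-period vocabulary, in developmental order.
period_levels <- function() c("preMZT", "early", "middle", "late")

stop_if_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", arg))
  }
}
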