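# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-variant draws are taken from a single seeded stream in canonical
# (sorted variant ID) order, which makes stochastic results reproducible and
# invariant to the row order of the input while keeping one healthy RNG
# stream (many streams from related seeds are measurably cross-correlated
# with the Mersenne-Twister seeding).
canonical_order <- function(id) order(id)

# Two-sided normal p-value with the degenerate zero-SE case mapped to the
# zero-statistic limit (p = 1 when the estimate is also 0).
normal_pvalue <- function(beta, se) {
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  2 * pnorm(-abs(z))
}

Z975 <- qnorm(0.975)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
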