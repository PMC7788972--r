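# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded operations never perturb global randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` reproducible sub-seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Dirichlet draw via normalized gamma variates; alpha may contain zeros
# (those components are exactly zero in the draw). Components below the
# detection floor are set to exactly 0, mimicking the detection limit of
# real profiling pipelines (a function is either absent or supported by
# at least ~1 read in 1e8) and keeping all retained abundances well
# inside double precision.
.ABUNDANCE_FLOOR <- 1e-8
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(x)
  if (s == 0) return(x)
  x <- x / s
  x[x < .ABUNDANCE_FLOOR] <- 0
  x / sum(x)
}
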