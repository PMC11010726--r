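# Internal helpers: classed conditions and scoped RNG.

fgs_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "fgs_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so no generator leaks global state.
with_seed <- function(seed, code) {
  if (!is_count(abs(seed) + 1)) {
    fgs_abort("`seed` must be a single integer", "fgs_parameter_error")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds derived from a parent seed, kept within the
# 32-bit integer range R requires.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Lognormal multiplicative noise with mean exactly 1 and the requested
# coefficient of variation (cv = 0 degenerates to 1).
rln_mean1 <- function(n, cv) {
  if (cv < 0) fgs_abort("coefficient of variation must be >= 0",
                        "fgs_parameter_error")
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log1p(cv^2))
  exp(rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}
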