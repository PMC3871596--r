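# Scoped RNG helpers: every stochastic operation takes an explicit seed and
# restores the caller's RNG state on exit, so package calls never perturb a
# user's random stream.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  list(
    sample = function(x, size) sample(x, size),
    runif = function(n, min = 0, max = 1) stats::runif(n, min, max),
    rnorm = function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd),
    rgamma = function(n, shape) stats::rgamma(n, shape = shape),
    sub_seeds = function(k) sample.int(.Machine$integer.max - 1L, k),
    restore = restore
  )
}

# Derive k reproducible child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, k) {
  rng <- local_rng(seed)
  on.exit(rng$restore())
  rng$sub_seeds(k)
}

frob <- function(M) sqrt(sum(M^2))

# Pairwise Euclidean distances between columns of X (d x n) -> n x n.
col_dist <- function(X) {
  as.matrix(stats::dist(t(X)))
}
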