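# Shared fixtures, built in code at test time.

# Two-class synthetic cohort (proliferating-like vs necrotic-like classes).
make_two_class <- function(n_a = 15, n_b = 20, noise_sd = 0.005, overlap = 0,
                           seed = 1, te_mode = "STE",
                           classes = c("a2", "me")) {
  protos <- make_prototype_sources(mrs_axis(), te_mode)
  generate_dataset(protos[classes],
                   stats::setNames(c(n_a, n_b), classes),
                   noise_sd = noise_sd, overlap = overlap, seed = seed)
}

# Tiny separable column blobs for factorization tests: k groups of columns
# around well-separated centers.
make_blobs <- function(k = 2, per = 10, d = 6, sep = 8, noise = 0.3,
                       seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(d * k), d, k) * 0 +
    sep * diag(1, d, k)[, seq_len(k), drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(k), function(j) {
    centers[, j] + matrix(stats::rnorm(d * per, sd = noise), d, per)
  }))
  list(X = X, truth = rep(seq_len(k), each = per))
}

# Agreement of two partitions up to label permutation (k <= 4).
partitions_agree <- function(a, b) {
  ka <- sort(unique(a)); kb <- sort(unique(b))
  if (length(ka) != length(kb)) return(FALSE)
  perms <- combinat_perms(length(kb))
  for (p in perms) {
    if (all(match(a, ka) == p[match(b, kb)])) return(TRUE)
  }
  FALSE
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

col_dist_oracle <- function(X) as.matrix(stats::dist(t(X)))

# Brute-force multi-start oracle for embeddings: direct optimization of the
# stress over free coordinates, best of `starts` random initializations.
brute_force_stress <- function(D, q, type = c("sammon", "raw"),
                               starts = 100, seed = 7) {
  type <- match.arg(type)
  n <- nrow(D)
  lower <- lower.tri(D)
  c_norm <- sum(D[lower])
  obj <- function(y) {
    Y <- matrix(y, n, q)
    E <- as.matrix(stats::dist(Y))
    if (type == "sammon")
      sum((D[lower] - E[lower])^2 / D[lower]) / c_norm
    else
      sum((D[lower] - E[lower])^2)
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(starts)) {
    y0 <- stats::rnorm(n * q, sd = mean(D) / 2 + 0.1)
    fit <- stats::optim(y0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

euclid_D <- function(n, q, seed) {
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * q), n, q)
  list(D = as.matrix(stats::dist(Y)), Y = Y)
}

# Small logistic posterior model (2 classes, linear decision function) used
# as a closed-form oracle for the Fisher metric.
make_logistic_model <- function(w, b = 0) {
  d <- length(w)
  # exact logistic: huge hidden layer not needed; use near-linear tanh trick
  # with tiny input scale absorbed into W2.
  s <- 1e-6
  structure(list(W1 = matrix(s * w, 1, d), b1 = 0,
                 W2 = matrix(c(1 / s, -1 / s) / 2, 2, 1),
                 b2 = c(b / 2, -b / 2),
                 classes = c("pos", "neg")),
            class = "posterior_model")
}
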