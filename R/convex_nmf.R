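#' Positive and negative parts of a matrix
#'
#' `positive_part` keeps entries greater than zero and zeroes the rest;
#' `negative_part` returns the magnitudes of negative entries (itself a
#' non-negative matrix). For any M, `M = positive_part(M) - negative_part(M)`.
#' These decompositions let the multiplicative updates handle mixed-sign
#' data — essential for long-echo-time spectra, whose inverted doublets make
#' it inappropriate to force the sources themselves to be non-negative.
#'
#' @param M real matrix.
#' @return matrix of the same shape.
#' @export
positive_part <- function(M) {
  M[M < 0] <- 0
  M
}

#' @rdname positive_part
#' @export
negative_part <- function(M) {
  M[M > 0] <- 0
  -M
}

#' K-means initialization for Convex-NMF
#'
#' Clusters the columns of X with K-means (best of `restarts` starts by
#' within-cluster sum of squares) and builds the standard smoothed indicator
#' initialization: with G the n x k one-hot cluster-indicator matrix and E
#' all ones, H0 = (G + 0.2 E)' and W0 = (G + 0.2 E) Dn^-1 where Dn is the
#' diagonal matrix of cluster sizes. Both factors are strictly positive, a
#' requirement of the multiplicative updates.
#'
#' @param X d x n data matrix (columns are cases; mixed sign allowed).
#' @param k number of sources, 1 <= k <= n.
#' @param restarts K-means restarts. Default 10.
#' @param seed integer RNG seed.
#' @param smoothing the additive constant, default 0.2.
#' @return list with `W0` (n x k), `H0` (k x n), `cluster` (K-means
#'   partition).
#' @export
kmeans_init <- function(X, k, restarts = 10L, seed = 1L, smoothing = 0.2) {
  n <- ncol(X)
  if (k > n) stop("k (", k, ") cannot exceed number of cases (", n, ")")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  if (k == n) {
    clu <- seq_len(n)
  } else {
    km <- NULL
    for (attempt in 1:5) {
      km <- tryCatch(stats::kmeans(t(X), centers = k, nstart = restarts),
                     error = function(e) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == k) break
      km <- NULL
    }
    if (is.null(km)) stop("K-means failed to find ", k, " non-empty clusters")
    clu <- km$cluster
  }
  G <- outer(clu, seq_len(k), "==") * 1
  sizes <- colSums(G)
  Gs <- G + smoothing
  W0 <- sweep(Gs, 2, sizes, "/")
  H0 <- t(Gs)
  list(W0 = W0, H0 = H0, cluster = clu)
}

cnmf_error <- function(X, W, G) frob(X - X %*% W %*% t(G))

#' Fit Convex-NMF by multiplicative updates
#'
#' Factorizes X ~ X W H with W (n x k) and H (k x n) non-negative, so each
#' source S = X W is a convex-like combination of observed cases and each
#' case is a non-negative mixture of sources. The data may contain negative
#' values. Updates alternate the standard multiplicative rules built from
#' the positive and negative parts of X'X, which never increase the
#' Frobenius reconstruction error; iteration stops when the error changes by
#' less than `tol` between successive iterations (relative change by
#' default, which is scale-invariant for unit-norm spectra; set
#' `mode = "absolute"` for the absolute-difference rule).
#'
#' @param X d x n data matrix.
#' @param k number of sources.
#' @param init optional list with positive `W0`, `H0` (e.g. from
#'   [kmeans_init()]); computed via [kmeans_init()] when `NULL`.
#' @param tol convergence threshold on the reconstruction-error change.
#'   Default 1e-5.
#' @param max_iter iteration budget. Default 2000.
#' @param mode `"relative"` (default) or `"absolute"` stopping rule.
#' @param restarts,seed forwarded to [kmeans_init()] when `init` is `NULL`.
#' @return object of class `convex_nmf`: `W`, `H`, `S = X %*% W`, `k`,
#'   `objective_trace`, `converged`, `iterations`, `init_cluster`.
#' @export
fit_convex_nmf <- function(X, k, init = NULL, tol = 1e-5, max_iter = 2000L,
                           mode = c("relative", "absolute"), restarts = 10L,
                           seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  init_cluster <- NULL
  if (is.null(init)) {
    init <- kmeans_init(X, k, restarts = restarts, seed = seed)
    init_cluster <- init$cluster
  }
  W <- as.matrix(init$W0)
  G <- t(as.matrix(init$H0))
  if (any(W <= 0) || any(G <= 0)) stop("initialization must be positive")
  A <- crossprod(X)                       # X'X, n x n
  Ap <- positive_part(A)
  An <- negative_part(A)
  floor_den <- function(M) pmax(M, 1e-12)
  err <- cnmf_error(X, W, G)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- err
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    ApW <- Ap %*% W; AnW <- An %*% W
    G <- G * sqrt((ApW + G %*% crossprod(W, AnW)) /
                    floor_den(AnW + G %*% crossprod(W, ApW)))
    GtG <- crossprod(G)
    W <- W * sqrt((Ap %*% G + AnW %*% GtG) /
                    floor_den(An %*% G + Ap %*% W %*% GtG))
    err_new <- cnmf_error(X, W, G)
    if (is.na(err_new)) stop("NaN reconstruction error at iteration ", it)
    trace[it + 1L] <- err_new
    delta <- if (mode == "relative")
      abs(err - err_new) / max(err, 1e-300) else abs(err - err_new)
    err <- err_new
    if (delta < tol) { converged <- TRUE; break }
  }
  trace <- trace[seq_len(it + 1L)]
  structure(list(W = W, H = t(G), S = X %*% W, X = X, k = k,
                 objective_trace = trace, converged = converged,
                 iterations = it, init_cluster = init_cluster),
            class = "convex_nmf")
}

#' @export
print.convex_nmf <- function(x, ...) {
  cat(sprintf(
    "convex_nmf: k = %d, %d cases, %d iterations (%sconverged), error %.4g\n",
    x$k, nrow(x$W), x$iterations, if (x$converged) "" else "not ",
    x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Mixing matrix for new data under fixed sources
#'
#' Holds the sources S fixed and iterates the multiplicative update for the
#' mixing matrix only, expressing new cases as non-negative mixtures of the
#' already-extracted sources. This is the mechanism for labeling an
#' independent test set with training-derived sources.
#'
#' @param model a fitted `convex_nmf`, or a d x k source matrix S.
#' @param X_new d x m matrix of new cases.
#' @param tol,max_iter stopping rule, as in [fit_convex_nmf()] (the fit's
#'   rule is reused).
#' @param mode `"relative"` or `"absolute"`.
#' @return k x m non-negative mixing matrix H_new.
#' @export
transform_fixed_sources <- function(model, X_new, tol = 1e-5,
                                    max_iter = 2000L,
                                    mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  S <- if (inherits(model, "convex_nmf")) model$S else as.matrix(model)
  X_new <- as.matrix(X_new)
  if (nrow(X_new) != nrow(S)) stop("X_new rows must match source length")
  k <- ncol(S)
  m <- ncol(X_new)
  P <- crossprod(X_new, S)                # m x k
  Q <- crossprod(S)                       # k x k
  Pp <- positive_part(P); Pn <- negative_part(P)
  Qp <- positive_part(Q); Qn <- negative_part(Q)
  G <- matrix(0.5, m, k)
  floor_den <- function(M) pmax(M, 1e-12)
  err <- frob(X_new - S %*% t(G))
  for (it in seq_len(max_iter)) {
    G <- G * sqrt((Pp + G %*% Qn) / floor_den(Pn + G %*% Qp))
    err_new <- frob(X_new - S %*% t(G))
    delta <- if (mode == "relative")
      abs(err - err_new) / max(err, 1e-300) else abs(err - err_new)
    err <- err_new
    if (delta < tol) break
  }
  t(G)
}

#' Normalize sources to unit length, compensating the mixing matrix
#'
#' Corrects scaling artifacts of the factorization: each source column of S
#' is scaled to unit Euclidean norm, the corresponding row of H is
#' multiplied by the removed norm, and W is rescaled so S = X W still holds;
#' the product X W H is unchanged. A zero-norm source is flagged as
#' degenerate and left unscaled.
#'
#' @param model a fitted `convex_nmf`.
#' @return the model with rescaled `S`, `W`, `H` and a logical `degenerate`
#'   vector marking zero-norm sources.
#' @export
rescale_sources <- function(model) {
  stopifnot(inherits(model, "convex_nmf"))
  nrm <- sqrt(colSums(model$S^2))
  degenerate <- nrm == 0
  scl <- ifelse(degenerate, 1, nrm)
  model$S <- sweep(model$S, 2, scl, "/")
  model$W <- sweep(model$W, 2, scl, "/")
  model$H <- sweep(model$H, 1, scl, "*")
  model$degenerate <- degenerate
  model
}
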