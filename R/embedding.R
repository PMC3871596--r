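# Distance-preserving embeddings of a Fisher (or any) distance matrix into a
# low-dimensional Euclidean space. All three methods start from the
# deterministic classical (Torgerson) MDS configuration, so they need no
# random initialization and method comparisons are not confounded by seeds.
# Duplicate points (zero off-diagonal distance) are merged before
# optimization and their coordinates copied back afterwards.

as_dist_matrix <- function(D) {
  if (inherits(D, "fisher_distances")) D <- D$D
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  D
}

# Merge duplicate points: returns representative indices and the group id of
# every original point.
merge_duplicates <- function(D) {
  n <- nrow(D)
  group <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (D[i, reps[r]] <= 0) { hit <- r; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    group[i] <- hit
  }
  list(reps = reps, group = group)
}

classical_mds_init <- function(D, q) {
  n <- nrow(D)
  cfg <- suppressWarnings(stats::cmdscale(D, k = min(q, n - 1)))
  Y <- matrix(0, n, q)
  if (length(cfg)) Y[, seq_len(ncol(cfg))] <- cfg
  Y
}

pair_dists <- function(Y) as.matrix(stats::dist(Y))

sammon_stress <- function(D, Y, lower) {
  E <- pair_dists(Y)
  sum((D[lower] - E[lower])^2 / D[lower]) / sum(D[lower])
}

raw_stress <- function(D, Y, lower) {
  E <- pair_dists(Y)
  sum((D[lower] - E[lower])^2)
}

finish_embedding <- function(Y_rep, dup, method, trace, extra = list()) {
  Y <- Y_rep[dup$group, , drop = FALSE]
  structure(c(list(coords = Y, method = method, stress_trace = trace,
                   q = ncol(Y), dup = dup), extra),
            class = "mrs_embedding")
}

#' @export
print.mrs_embedding <- function(x, ...) {
  cat(sprintf("mrs_embedding (%s): %d points -> %d dims, final stress %.3g\n",
              x$method, nrow(x$coords), x$q,
              x$stress_trace[length(x$stress_trace)]))
  invisible(x)
}

#' Sammon mapping of a distance matrix
#'
#' Minimizes Sammon's stress
#' E = (1 / sum d_ij) sum (d_ij - e_ij)^2 / d_ij over pairs i < j, where d
#' are the input (Fisher) distances and e the embedded Euclidean distances.
#' The 1/d weighting emphasizes the preservation of small distances, i.e.
#' local neighborhood structure. Optimization is gradient descent with step
#' halving from the classical-MDS configuration; the stress trace is
#' non-increasing by construction.
#'
#' @param D square symmetric distance matrix, or a `fisher_distances`.
#' @param q latent dimensionality, >= 1. Default 2.
#' @param max_iter iteration budget. Default 500.
#' @param tol relative stress-change convergence threshold. Default 1e-7.
#' @return an `mrs_embedding` with fields `coords` (n x q), `method`,
#'   `stress_trace`, and the merge bookkeeping for duplicates.
#' @export
embed_sammon <- function(D, q = 2L, max_iter = 500L, tol = 1e-7) {
  D_full <- as_dist_matrix(D)
  dup <- merge_duplicates(D_full)
  Dm <- D_full[dup$reps, dup$reps, drop = FALSE]
  n <- nrow(Dm)
  if (n == 1)
    return(finish_embedding(matrix(0, 1, q), dup, "sammon", 0))
  lower <- lower.tri(Dm)
  c_norm <- sum(Dm[lower])
  Y <- classical_mds_init(Dm, q)
  stress <- sammon_stress(Dm, Y, lower)
  trace <- stress
  step <- 0.1
  for (it in seq_len(max_iter)) {
    E <- pair_dists(Y)
    W <- matrix(0, n, n)
    ok <- E > 0
    W[ok] <- (Dm[ok] - E[ok]) / (Dm[ok] * E[ok])
    diag(W) <- 0
    # grad of stress wrt Y: (-2/c) * sum_j W_ij (y_i - y_j)
    G <- (-2 / c_norm) * (rowSums(W) * Y - W %*% Y)
    accepted <- FALSE
    while (step > 1e-14) {
      Y_new <- Y - step * G
      s_new <- sammon_stress(Dm, Y_new, lower)
      if (is.finite(s_new) && s_new <= stress) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    conv <- (stress - s_new) <= tol * max(stress, 1e-300)
    Y <- Y_new; stress <- s_new; step <- step * 1.5
    trace <- c(trace, stress)
    if (conv) break
  }
  finish_embedding(Y, dup, "sammon", trace)
}

smacof_bmat <- function(Dm, E) {
  n <- nrow(Dm)
  B <- matrix(0, n, n)
  ok <- E > 0
  B[ok] <- -Dm[ok] / E[ok]
  diag(B) <- 0
  diag(B) <- -rowSums(B)
  B
}

#' Metric multidimensional scaling by SMACOF majorization
#'
#' Minimizes the raw stress sum (d_ij - e_ij)^2 by the SMACOF (scaling by
#' majorizing a convex function) algorithm: each iteration applies the
#' Guttman transform, which is guaranteed never to increase the stress.
#' Initialization is classical MDS.
#'
#' @inheritParams embed_sammon
#' @return an `mrs_embedding`.
#' @export
embed_mds <- function(D, q = 2L, max_iter = 500L, tol = 1e-7) {
  D_full <- as_dist_matrix(D)
  dup <- merge_duplicates(D_full)
  Dm <- D_full[dup$reps, dup$reps, drop = FALSE]
  n <- nrow(Dm)
  if (n == 1)
    return(finish_embedding(matrix(0, 1, q), dup, "mds", 0))
  lower <- lower.tri(Dm)
  Y <- classical_mds_init(Dm, q)
  stress <- raw_stress(Dm, Y, lower)
  trace <- stress
  for (it in seq_len(max_iter)) {
    E <- pair_dists(Y)
    B <- smacof_bmat(Dm, E)
    Y_new <- (B %*% Y) / n                     # Guttman transform
    s_new <- raw_stress(Dm, Y_new, lower)
    conv <- (stress - s_new) <= tol * max(stress, 1e-300)
    if (s_new <= stress) {
      Y <- Y_new; stress <- s_new
      trace <- c(trace, stress)
    }
    if (conv) break
  }
  finish_embedding(Y, dup, "mds", trace)
}

#' Parametric embedding by iterative majorization (IMA)
#'
#' Expresses the latent position of point i as a linear combination of
#' Gaussian basis functions of its Fisher distances to a set of training
#' centers: y_i = V' phi(i), phi_j(i) = exp(-d(i, c_j)^2 / (2 sigma^2)).
#' The raw stress is minimized over the weight matrix V by iterative
#' majorization: each iteration majorizes the stress at the current
#' configuration and solves the resulting ridge-regularized least-squares
#' subproblem in closed form. Because the mapping is parametric, new points
#' embed by evaluating the same basis expansion ([embed_out_of_sample()]).
#'
#' @inheritParams embed_sammon
#' @param centers indices of training points used as basis centers; default
#'   all points.
#' @param sigma kernel width in Fisher-distance units; default the median
#'   off-diagonal distance.
#' @param ridge L2 regularization of the subproblem. Default 1e-8.
#' @return an `mrs_embedding` with additional fields `V` (m x q weights),
#'   `centers`, `sigma`.
#' @export
embed_ima <- function(D, q = 2L, centers = NULL, sigma = NULL, ridge = 1e-8,
                      max_iter = 500L, tol = 1e-7) {
  D_full <- as_dist_matrix(D)
  dup <- merge_duplicates(D_full)
  Dm <- D_full[dup$reps, dup$reps, drop = FALSE]
  n <- nrow(Dm)
  if (is.null(centers)) centers <- seq_len(n)
  if (any(centers < 1 | centers > n)) stop("centers must index training points")
  if (is.null(sigma)) {
    off <- Dm[lower.tri(Dm)]
    sigma <- stats::median(off[off > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (n == 1)
    return(finish_embedding(matrix(0, 1, q), dup, "ima", 0,
                            list(V = matrix(0, length(centers), q),
                                 centers = centers, sigma = sigma)))
  lower <- lower.tri(Dm)
  Phi <- exp(-Dm[, centers, drop = FALSE]^2 / (2 * sigma^2))   # n x m
  m <- ncol(Phi)
  # majorizer quadratic term: V_w = n I - 11' (unweighted raw stress)
  PtVP <- n * crossprod(Phi) - tcrossprod(colSums(Phi))
  Y0 <- classical_mds_init(Dm, q)
  V <- tryCatch(solve(PtVP + ridge * diag(m), crossprod(Phi, scale(Y0, scale = FALSE) * n)),
                error = function(e) NULL)
  if (is.null(V)) {
    ridge <- ridge * 1e6
    warning("singular IMA subproblem; ridge increased to ", ridge)
    V <- solve(PtVP + ridge * diag(m), crossprod(Phi, scale(Y0, scale = FALSE) * n))
  }
  Y <- Phi %*% V
  stress <- raw_stress(Dm, Y, lower)
  trace <- stress
  for (it in seq_len(max_iter)) {
    E <- pair_dists(Y)
    B <- smacof_bmat(Dm, E)
    RHS <- crossprod(Phi, B %*% Y)
    V_new <- tryCatch(solve(PtVP + ridge * diag(m), RHS),
                      error = function(e) {
                        ridge <<- ridge * 1e6
                        warning("singular IMA subproblem; ridge increased to ",
                                ridge)
                        solve(PtVP + ridge * diag(m), RHS)
                      })
    Y_new <- Phi %*% V_new
    s_new <- raw_stress(Dm, Y_new, lower)
    conv <- (stress - s_new) <= tol * max(stress, 1e-300)
    if (s_new <= stress) {
      V <- V_new; Y <- Y_new; stress <- s_new
      trace <- c(trace, stress)
    }
    if (conv) break
  }
  finish_embedding(Y, dup, "ima", trace,
                   list(V = V, centers = centers, sigma = sigma,
                        rep_of_center = dup$reps[centers]))
}

#' Embed new points into a fitted configuration
#'
#' For an IMA model the parametric map is applied directly: the basis
#' expansion of the new point's Fisher distances to the stored centers,
#' times the fitted weights. For Sammon and MDS models each new point
#' minimizes its own stress contribution with the training coordinates
#' frozen, starting from the coordinates of its nearest training neighbor,
#' so the refit can only improve on that initialization.
#'
#' @param model an `mrs_embedding`.
#' @param D_new m x n matrix of new-to-train distances (e.g. from
#'   [extend_distances()]).
#' @return m x q matrix of latent coordinates.
#' @export
embed_out_of_sample <- function(model, D_new) {
  stopifnot(inherits(model, "mrs_embedding"))
  D_new <- as.matrix(D_new)
  n <- nrow(model$coords)
  if (ncol(D_new) != n)
    stop("D_new must have one column per training point (", n, ")")
  m <- nrow(D_new)
  q <- model$q
  if (m == 0) return(matrix(0, 0, q))
  if (model$method == "ima") {
    Dc <- D_new[, model$rep_of_center, drop = FALSE]
    Phi <- exp(-Dc^2 / (2 * model$sigma^2))
    return(Phi %*% model$V)
  }
  Yt <- model$coords
  sammon <- model$method == "sammon"
  out <- matrix(0, m, q)
  for (i in seq_len(m)) {
    d <- D_new[i, ]
    w <- if (sammon) ifelse(d > 0, 1 / d, 0) else rep(1, n)
    obj <- function(y) {
      e <- sqrt(colSums((t(Yt) - y)^2))
      sum(w * (d - e)^2)
    }
    y0 <- Yt[which.min(d), ]
    fit <- stats::optim(y0, obj, method = "BFGS",
                        control = list(maxit = 200))
    out[i, ] <- if (fit$value <= obj(y0)) fit$par else y0
  }
  out
}
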