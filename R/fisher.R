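#' Fisher Information metric field induced by a posterior model
#'
#' Wraps a fitted [fit_posterior()] model as a position-dependent Riemannian
#' metric on the data space: at each point x the metric tensor is
#' J(x) = sum_c p(c|x) g_c(x) g_c(x)^T + eps I, where g_c = grad_x log p(c|x).
#' The metric expands directions along which the predicted class membership
#' changes rapidly and compresses uninformative ones. With C classes the raw
#' tensor has rank at most C - 1, so a small ridge `eps` keeps it positive
#' definite.
#'
#' @param model a `posterior_model`.
#' @param eps non-negative diagonal ridge. `NULL` (default) defers the
#'   choice to [geodesic_distance_matrix()], which sets it to 1e-6 times the
#'   mean diagonal of J over the training points; a `metric_field` used
#'   standalone defaults to 0.
#' @return object of class `fisher_field` (also `metric_field`).
#' @export
metric_field <- function(model, eps = NULL) {
  stopifnot(inherits(model, "posterior_model"))
  structure(list(model = model, eps = eps),
            class = c("fisher_field", "metric_field"))
}

#' Constant (flat) metric field
#'
#' A synthetic field with the same fixed symmetric PSD tensor everywhere.
#' Under a constant metric geodesics are straight lines and the geodesic
#' distance has the Mahalanobis closed form sqrt(dx' A dx), which makes this
#' field the reference oracle for the graph-based geodesic approximation.
#'
#' @param A symmetric positive semi-definite d x d matrix.
#' @return object of class `constant_field` (also `metric_field`).
#' @export
constant_field <- function(A) {
  A <- as.matrix(A)
  if (max(abs(A - t(A))) > 1e-10) stop("A must be symmetric")
  structure(list(A = A, eps = 0), class = c("constant_field", "metric_field"))
}

field_eps <- function(field) if (is.null(field$eps)) 0 else field$eps

#' Evaluate the metric tensor at a point
#'
#' @param field a `metric_field`.
#' @param x point (spectrum vector).
#' @return d x d symmetric PSD matrix J(x).
#' @export
fisher_matrix <- function(field, x) {
  UseMethod("fisher_matrix")
}

#' @export
fisher_matrix.fisher_field <- function(field, x) {
  G <- posterior_log_gradient(field$model, x)        # C x d
  if (!all(is.finite(G)))
    stop("non-finite posterior gradient for class ",
         which(!apply(is.finite(G), 1, all))[1])
  p <- as.numeric(predict_posterior(field$model, x))
  J <- crossprod(G * sqrt(p))                        # sum_c p_c g_c g_c'
  J + field_eps(field) * diag(nrow(J))
}

#' @export
fisher_matrix.constant_field <- function(field, x) field$A

# Quadratic form dx' J(at) dx without materializing J; `At` and `Dx` are
# d x m matrices of evaluation points and displacements (paired columns).
quad_form_at <- function(field, At, Dx) {
  UseMethod("quad_form_at")
}

#' @export
quad_form_at.constant_field <- function(field, At, Dx) {
  colSums(Dx * (field$A %*% Dx))
}

#' @export
quad_form_at.fisher_field <- function(field, At, Dx) {
  m <- field$model
  Z <- tanh(m$W1 %*% At + m$b1)                      # h x m
  A <- m$W2 %*% Z + m$b2
  A <- sweep(A, 2, apply(A, 2, max), "-")
  P <- exp(A); P <- sweep(P, 2, colSums(P), "/")     # C x m
  U <- (m$W1 %*% Dx) * (1 - Z^2)                     # h x m
  Tm <- m$W2 %*% U                                   # C x m: a-space Jacobian . dx
  Tc <- sweep(Tm, 2, colSums(P * Tm), "-")           # (e_c - p)-projected
  colSums(P * Tc^2) + field_eps(field) * colSums(Dx^2)
}

#' Local Fisher distance between two neighboring points
#'
#' First-order distance sqrt(dx' J(m) dx) with the metric evaluated at the
#' segment midpoint m = (x1 + x2) / 2 — symmetric in its arguments and
#' second-order accurate for the geodesic path integral on short segments.
#'
#' @param field a `metric_field`.
#' @param x1,x2 points of equal dimension.
#' @return non-negative scalar.
#' @export
local_distance <- function(field, x1, x2) {
  if (length(x1) != length(x2)) stop("points must have equal dimension")
  mid <- matrix((x1 + x2) / 2, ncol = 1)
  dx <- matrix(x2 - x1, ncol = 1)
  sqrt(max(quad_form_at(field, mid, dx), 0))
}

# All-pairs single-segment local distances between columns of X -> n x n.
pairwise_local <- function(field, X) {
  n <- ncol(X)
  L <- matrix(0, n, n)
  if (n < 2) return(L)
  ij <- utils::combn(n, 2)
  At <- (X[, ij[1, ], drop = FALSE] + X[, ij[2, ], drop = FALSE]) / 2
  Dx <- X[, ij[2, ], drop = FALSE] - X[, ij[1, ], drop = FALSE]
  v <- sqrt(pmax(quad_form_at(field, At, Dx), 0))
  L[t(ij)] <- v
  L[t(ij[2:1, , drop = FALSE])] <- v
  L
}

# Path-integral edge weights for endpoint pairs (columns of Xa to Xb),
# summing local segment distances over `subdivisions` straight-line pieces
# with the metric at each segment midpoint.
edge_lengths <- function(field, Xa, Xb, subdivisions) {
  S <- max(1L, as.integer(subdivisions))
  Dx <- (Xb - Xa) / S
  total <- 0
  for (s in seq_len(S)) {
    At <- Xa + (s - 0.5) * Dx
    total <- total + sqrt(pmax(quad_form_at(field, At, Dx), 0))
  }
  total
}

# Ridge default: 1e-6 x mean diagonal of J over the training points.
auto_eps <- function(field, X) {
  if (!inherits(field, "fisher_field") || !is.null(field$eps)) return(field)
  m <- field$model
  d <- nrow(X)
  tr <- vapply(seq_len(ncol(X)), function(j) {
    G <- posterior_log_gradient(m, X[, j])
    p <- as.numeric(predict_posterior(m, X[, j]))
    sum(p * rowSums(G^2))                            # trace of J(x_j)
  }, numeric(1))
  field$eps <- 1e-6 * mean(tr) / d
  field
}

#' Geodesic Fisher distance matrix over a dataset
#'
#' Approximates pairwise geodesic distances under the metric field by
#' shortest paths on a neighborhood graph: each case is linked to its
#' `k_neighbors` nearest cases by local Fisher distance, edge weights are
#' path integrals along the straight segment (midpoint rule over
#' `subdivisions` pieces), and a minimum-spanning-tree over the local
#' distances is added so the graph is always connected. All-pairs shortest
#' paths then give a symmetric, zero-diagonal distance matrix satisfying the
#' triangle inequality by construction.
#'
#' @param field a `metric_field`. For a `fisher_field` with `eps = NULL` the
#'   ridge is set automatically (see [metric_field()]).
#' @param X d x n matrix of points in columns (UL2-normalized spectra, the
#'   space the classifier was trained in).
#' @param k_neighbors neighborhood size, >= 1. Default 10.
#' @param subdivisions segments per edge for the path-integral quadrature.
#'   Default 4.
#' @return object of class `fisher_distances`: `D` (n x n), `case_ids`,
#'   `k`, `subdivisions`, `eps`, plus the graph internals used by
#'   [extend_distances()].
#' @export
geodesic_distance_matrix <- function(field, X, k_neighbors = 10L,
                                     subdivisions = 4L) {
  n <- ncol(X)
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  field <- auto_eps(field, X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("case_", seq_len(n))
  if (n < 2) {
    return(structure(list(D = matrix(0, n, n), case_ids = ids,
                          k = k_neighbors, subdivisions = subdivisions,
                          eps = field_eps(field), field = field, X = X),
                     class = "fisher_distances"))
  }
  L <- pairwise_local(field, X)
  k <- min(k_neighbors, n - 1L)
  # union of k-NN edges and the MST of the complete local-distance graph
  nn_edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    ord <- order(L[i, ])[seq_len(k + 1L)]
    ord <- setdiff(ord, i)[seq_len(k)]
    cbind(i, ord)
  }))
  g_full <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                                weighted = TRUE)
  mst <- igraph::mst(g_full)
  mst_edges <- igraph::as_edgelist(mst, names = FALSE)
  edges <- rbind(nn_edges, mst_edges)
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  w <- edge_lengths(field, X[, edges[, 1], drop = FALSE],
                    X[, edges[, 2], drop = FALSE], subdivisions)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::E(g)$weight <- w
  D <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(D) <- list(ids, ids)
  structure(list(D = D, case_ids = ids, k = k_neighbors,
                 subdivisions = subdivisions, eps = field_eps(field),
                 field = field, X = X),
            class = "fisher_distances")
}

#' @export
print.fisher_distances <- function(x, ...) {
  cat(sprintf(
    "fisher_distances: %d x %d (k = %d, subdivisions = %d, eps = %.3g)\n",
    nrow(x$D), ncol(x$D), x$k, x$subdivisions, x$eps))
  invisible(x)
}

#' Fisher distances from new points to the training set
#'
#' Out-of-sample extension of [geodesic_distance_matrix()]: each new point
#' is attached to its k nearest training points by local Fisher distance
#' (path-integral edge weights, same quadrature as training), and its
#' distance to every training point j is the minimum over attachments a of
#' `edge(new, a) + D(a, j)`. Training distances are unchanged.
#'
#' @param train_D a `fisher_distances` object from the training run.
#' @param new_X d x m matrix of new points in columns.
#' @return m x n matrix of new-to-train distances.
#' @export
extend_distances <- function(train_D, new_X) {
  stopifnot(inherits(train_D, "fisher_distances"))
  X <- train_D$X
  field <- train_D$field
  n <- ncol(X)
  m <- ncol(new_X)
  if (m == 0) return(matrix(0, 0, n, dimnames = list(NULL, train_D$case_ids)))
  if (nrow(new_X) != nrow(X)) stop("dimension mismatch with training points")
  k <- min(train_D$k, n)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) {
    x <- new_X[, i]
    At <- (X + x) / 2
    Dx <- X - x
    l1 <- sqrt(pmax(quad_form_at(field, At, Dx), 0))
    anchors <- order(l1)[seq_len(k)]
    w <- edge_lengths(field, matrix(x, nrow(X), length(anchors)),
                      X[, anchors, drop = FALSE], train_D$subdivisions)
    cand <- sweep(train_D$D[anchors, , drop = FALSE], 1, w, "+")
    out[i, ] <- apply(cand, 2, min)
  }
  colnames(out) <- train_D$case_ids
  out
}
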