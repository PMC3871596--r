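test_that("fisher matrix matches the logistic closed form p(1-p) w w'", {
  set.seed(21)
  w <- rnorm(6)
  model <- make_logistic_model(w, b = 0.3)
  field <- metric_field(model, eps = 0)
  for (i in 1:5) {
    x <- rnorm(6)
    p <- as.numeric(predict_posterior(model, x))[1]
    J <- fisher_matrix(field, x)
    expect_equal(J, p * (1 - p) * tcrossprod(w), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("fisher matrix is symmetric PSD with eigenvalues >= eps", {
  gen <- make_two_class(12, 12, seed = 3)
  sp <- split_dataset(gen$dataset, seed = 3)
  model <- fit_posterior(sp$train, sp$holdout, seed = 3)
  field <- metric_field(model, eps = 1e-6)
  x <- gen$dataset$X[, 5]
  J <- fisher_matrix(field, x)
  expect_equal(J, t(J))
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 1e-6 - 1e-10))
  # zero-weight (constant posterior) model, eps 0 -> zero matrix
  m0 <- model; m0$W2[] <- 0
  expect_equal(max(abs(fisher_matrix(metric_field(m0, eps = 0), x))), 0)
})

test_that("local distance: symmetry, zero at equality, Euclidean under identity", {
  field <- constant_field(diag(4))
  x1 <- c(1, 2, 3, 4); x2 <- c(0, 1, -1, 2)
  expect_equal(local_distance(field, x1, x1), 0)
  expect_equal(local_distance(field, x1, x2), local_distance(field, x2, x1))
  expect_equal(local_distance(field, x1, x2), sqrt(sum((x1 - x2)^2)))
  expect_error(local_distance(field, x1, c(1, 2)), "equal dimension")
  # fisher field is symmetric in its arguments too (midpoint rule)
  model <- make_logistic_model(c(1, -2, 0.5, 1))
  ff <- metric_field(model, eps = 0)
  expect_equal(local_distance(ff, x1, x2), local_distance(ff, x2, x1))
})

test_that("geodesic matrix has metric properties and matches Mahalanobis on a line", {
  set.seed(31)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
  field <- constant_field(A)
  # dense sample along a segment: geodesics are straight -> closed form
  t_par <- sort(runif(40))
  dir <- c(1, -0.5, 2)
  X <- outer(c(0.3, -1, 0.2), rep(1, 40)) + outer(dir, t_par)
  fd <- geodesic_distance_matrix(field, X, k_neighbors = 5, subdivisions = 2)
  D <- fd$D
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 40), ignore_attr = TRUE)
  expect_true(all(D >= 0))
  # triangle inequality on sampled triples
  set.seed(32)
  for (r in 1:200) {
    ijk <- sample(40, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
  }
  maha <- sapply(seq_len(40), function(i) sapply(seq_len(40), function(j) {
    dx <- X[, i] - X[, j]; sqrt(sum(dx * (A %*% dx)))
  }))
  off <- upper.tri(D)
  expect_lt(max(abs(D[off] - maha[off]) / maha[off]), 0.05)
})

test_that("edge quadrature converges: doubling subdivisions changes little", {
  gen <- make_two_class(10, 10, seed = 6)
  sp <- split_dataset(gen$dataset, seed = 6)
  model <- fit_posterior(sp$train, sp$holdout, seed = 6)
  field <- metric_field(model, eps = 1e-8)
  X <- gen$dataset$X[, 1:12]
  w4 <- mrsnmf:::edge_lengths(field, X[, 1:6], X[, 7:12], 4)
  w8 <- mrsnmf:::edge_lengths(field, X[, 1:6], X[, 7:12], 8)
  expect_lt(max(abs(w8 - w4) / pmax(w4, 1e-12)), 0.02)
})

test_that("all-pairs result is equivariant under point permutation", {
  set.seed(41)
  X <- matrix(rnorm(3 * 15), 3)
  field <- constant_field(diag(3))
  D1 <- geodesic_distance_matrix(field, X, k_neighbors = 4)$D
  perm <- sample(15)
  D2 <- geodesic_distance_matrix(field, X[, perm], k_neighbors = 4)$D
  expect_equal(D2, D1[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("metric amplifies between-class separation for a trained model", {
  hits <- 0
  n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    gen <- make_two_class(10, 10, noise_sd = 0.01, seed = s)
    sp <- split_dataset(gen$dataset, seed = s)
    model <- fit_posterior(sp$train, sp$holdout, seed = s)
    field <- metric_field(model)
    fd <- geodesic_distance_matrix(field, gen$dataset$X, k_neighbors = 6)
    lab <- gen$dataset$labels
    between <- mean(fd$D[lab == "a2", lab == "me"])
    within <- (mean(fd$D[lab == "a2", lab == "a2"]) +
                 mean(fd$D[lab == "me", lab == "me"])) / 2
    E <- col_dist_oracle(gen$dataset$X)
    between_e <- mean(E[lab == "a2", lab == "me"])
    within_e <- (mean(E[lab == "a2", lab == "a2"]) +
                   mean(E[lab == "me", lab == "me"])) / 2
    if (between / within >= between_e / within_e) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("distance extension is exact for duplicated training points and on complete graphs", {
  set.seed(51)
  X <- matrix(rnorm(4 * 30), 4)
  field <- constant_field(diag(4))
  fd <- geodesic_distance_matrix(field, X, k_neighbors = 30, subdivisions = 1)
  # brute-force oracle: all-pairs rerun with the point included, one at a time
  new_pts <- matrix(rnorm(4 * 3), 4)
  ext <- extend_distances(fd, new_pts)
  for (j in 1:3) {
    full <- geodesic_distance_matrix(field, cbind(X, new_pts[, j]),
                                     k_neighbors = 30, subdivisions = 1)
    expect_equal(ext[j, ], full$D[31, 1:30], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_true(all(is.finite(ext)) && all(ext >= 0))
  # new point identical to training point i
  ext_i <- extend_distances(fd, X[, 7, drop = FALSE])
  expect_equal(as.numeric(ext_i), as.numeric(fd$D[7, ]), tolerance = 1e-9)
  expect_equal(as.numeric(ext_i[1, 7]), 0)
  # empty new set
  expect_equal(nrow(extend_distances(fd, X[, integer(0)])), 0)
})
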