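test_that("ul2 normalization is exact, idempotent and scale-invariant", {
  expect_equal(ul2_normalize(c(3, 4)), c(0.6, 0.8))
  set.seed(11)
  x <- rnorm(195)
  u <- ul2_normalize(x)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
  expect_equal(ul2_normalize(u), u)
  expect_equal(ul2_normalize(7.3 * x), u)
  M <- matrix(rnorm(20), 5)
  expect_equal(sqrt(colSums(ul2_normalize(M)^2)), rep(1, 4))
  expect_error(ul2_normalize(numeric(5)), "zero")
})

test_that("dataset constructor validates shape, axis and labels", {
  ppm <- mrs_axis(n = 5)
  X <- matrix(1, 5, 3)
  ds <- mrs_dataset(X, ppm, labels = c("A", "B", "A"))
  expect_identical(n_cases(ds), 3L)
  expect_error(mrs_dataset(X, ppm[-1]), "axis length")
  expect_error(mrs_dataset(X, rep(1, 5)), "monotone")
  expect_error(mrs_dataset(X, ppm, labels = "A"), "labels length")
  expect_error(mrs_dataset(X * NA, ppm), "finite")
  ax <- mrs_axis()
  expect_length(ax, 195)
  expect_true(all(diff(ax) < 0))
  expect_equal(range(ax), c(0.50, 4.24))
})

test_that("class means are exact for degenerate and two-member classes", {
  ppm <- mrs_axis(n = 4)
  a <- c(1, 2, 3, 4); b <- c(4, 3, 2, 1)
  ds <- mrs_dataset(cbind(a, b, a), ppm, labels = c("x", "y", "x"))
  expect_equal(class_mean_spectrum(ds, "y"), b)
  expect_equal(class_mean_spectrum(ds, "x"), a)
  ds2 <- mrs_dataset(cbind(a, b), ppm, labels = c("x", "y"))
  dsm <- mrs_dataset(cbind(a, b), ppm, labels = c("x", "x"))
  expect_equal(class_mean_spectrum(dsm, "x"), (a + b) / 2)
  expect_error(class_mean_spectrum(ds, "zz"), "not found")
  # identical columns -> class mean equals the column
  dsi <- mrs_dataset(cbind(a, a, a), ppm, labels = rep("x", 3))
  expect_equal(class_mean_spectrum(dsi, "x"), a)
})

test_that("generator class means concentrate on the prototype mean", {
  protos <- make_prototype_sources(mrs_axis(), "STE")
  gen <- generate_dataset(protos["a2"], c(a2 = 50), noise_sd = 0.01,
                          seed = 42)
  m <- ul2_normalize(class_mean_spectrum(gen$dataset, "a2"))
  proto_mean <- protos$a2$mean_spectrum
  # per-coordinate deviation within 3 sd / sqrt(50) of the draw spread
  dev <- abs(m - proto_mean)
  draw_sd <- apply(gen$dataset$X, 1, sd)
  expect_true(all(dev <= 3 * draw_sd / sqrt(50) + 3 * 0.01 / sqrt(50) + 1e-3))
  expect_gt(cor(m, proto_mean), 0.995)
})

test_that("stratified split is disjoint, exhaustive, sized and reproducible", {
  protos <- make_prototype_sources(mrs_axis(n = 30), "STE")
  gen <- generate_dataset(protos[c("a2", "gl")], c(a2 = 22, gl = 86),
                          noise_sd = 0.01, seed = 7)
  sp <- split_dataset(gen$dataset, fraction = 2 / 3, seed = 9)
  expect_equal(n_cases(sp$train), 72)     # round(2/3*22) + round(2/3*86)
  expect_equal(n_cases(sp$holdout), 36)
  expect_length(intersect(sp$train_idx, sp$holdout_idx), 0)
  expect_setequal(c(sp$train_idx, sp$holdout_idx), seq_len(108))
  # per-class stratification
  expect_equal(sum(sp$train$labels == "a2"), 15)
  sp2 <- split_dataset(gen$dataset, fraction = 2 / 3, seed = 9)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_dataset(gen$dataset, fraction = 1), "fraction")
  ds_small <- subset_cases(gen$dataset, c(1, 23, 24, 25, 26))
  expect_warning(split_dataset(ds_small, seed = 1), "kept entirely in train")
})

test_that("read/write round-trips both orientations, labels exactly", {
  protos <- make_prototype_sources(mrs_axis(n = 5), "STE")
  gen <- generate_dataset(protos, c(a2 = 1, gl = 1, me = 1), noise_sd = 0.02,
                          seed = 3)
  ds <- gen$dataset
  for (orient in c("cases-rows", "cases-cols")) {
    f <- tempfile(fileext = ".tsv")
    write_mrs(ds, f, orientation = orient)
    back <- read_mrs(f, orientation = orient)
    expect_equal(back$X, ds$X, tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(back$labels, ds$labels)
    expect_equal(back$ppm, ds$ppm, tolerance = 1e-9)
    unlink(f)
  }
  # single-case file
  f <- tempfile(fileext = ".tsv")
  write_mrs(subset_cases(ds, 1), f)
  expect_equal(n_cases(read_mrs(f)), 1)
  unlink(f)
})

test_that("reader reports parse errors with location", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("case_id\t1.0\t2.0\tlabel", "c1\t0.1\toops\tA"), f)
  expect_error(read_mrs(f), "non-numeric")
  unlink(f)
})

test_that("superclass merging relabels and rejects overlap", {
  ppm <- mrs_axis(n = 3)
  ds <- mrs_dataset(matrix(rnorm(12), 3), ppm,
                    labels = c("A2", "GL", "ME", "GL"))
  ag <- select_classes(ds, superclass = list(AG = c("GL", "ME")))
  expect_setequal(unique(ag$labels), c("A2", "AG"))
  expect_equal(sum(ag$labels == "AG"), 3)
  expect_error(select_classes(ds, superclass = list(AG = c("GL", "ME"),
                                                    XX = c("ME"))),
               "disjoint")
})
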