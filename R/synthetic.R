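#' Gaussian peak on a ppm axis
#'
#' Lineshape primitive used by the synthetic generator. Gaussian by default;
#' a Lorentzian option is provided for users who prefer the natural NMR
#' lineshape. Negative amplitudes encode inverted resonances (e.g. the
#' lactate doublet at long echo time).
#'
#' @param ppm ppm axis.
#' @param center peak position (ppm); must lie inside the axis window.
#' @param width half-width at half-maximum-like scale parameter (ppm), > 0.
#' @param amplitude peak amplitude; may be negative.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return numeric vector, the peak evaluated on the axis.
#' @export
peak_shape <- function(ppm, center, width, amplitude = 1,
                       shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (width <= 0) stop("peak width must be positive")
  if (center > max(ppm) || center < min(ppm))
    stop("peak center ", center, " outside axis window")
  if (shape == "gaussian") {
    amplitude * exp(-(ppm - center)^2 / (2 * width^2))
  } else {
    amplitude * width^2 / ((ppm - center)^2 + width^2)
  }
}

# Constituent tissue signatures, built from the metabolite peaks that
# characterize them in vivo:
#  * actively proliferating tissue: high choline (3.21 ppm), moderate
#    creatine (3.03 / 3.92 ppm), mI/Gly (3.55 ppm), some NAA (2.01 ppm),
#    low mobile lipids;
#  * necrotic tissue: dominant mobile lipids (1.29 / 0.90 ppm) and lactate
#    (1.33 ppm doublet).
# At long echo time the lactate doublet is inverted (negative) and the broad
# lipid components decay, so LTE signatures may contain negative values.
constituent_signatures <- function(ppm, te_mode) {
  lte <- te_mode == "LTE"
  prolif <-
    peak_shape(ppm, 3.21, 0.035, 1.00) +              # choline
    peak_shape(ppm, 3.03, 0.035, 0.55) +              # creatine
    peak_shape(ppm, 3.92, 0.040, 0.30) +              # creatine (CH2)
    peak_shape(ppm, 3.55, 0.045, 0.45) +              # mI / Gly
    peak_shape(ppm, 2.01, 0.050, if (lte) 0.30 else 0.40) +  # NAA region
    (if (lte) 0 else peak_shape(ppm, 1.29, 0.120, 0.10))     # trace lipids
  necro <-
    peak_shape(ppm, 0.90, if (lte) 0.070 else 0.110, if (lte) 0.35 else 0.80) +
    peak_shape(ppm, 1.29, if (lte) 0.060 else 0.130, if (lte) 0.45 else 1.00) +
    peak_shape(ppm, 3.21, 0.035, 0.15) +              # residual choline
    (if (lte)
      peak_shape(ppm, 1.36, 0.025, -0.60) +           # inverted lactate doublet
      peak_shape(ppm, 1.30, 0.025, -0.60)
     else
      peak_shape(ppm, 1.33, 0.030, 0.35))             # lactate atop lipids
  sig <- cbind(proliferating = prolif, necrotic = necro)
  if (!lte) sig[sig < 0] <- 0
  ul2_normalize(sig)
}

#' Class prototypes for synthetic brain-tumor MRS cohorts
#'
#' Returns three class prototypes that emulate the spectral structure of the
#' tumor types studied with this method: a low-grade astrocytoma-like class
#' (`a2`, almost purely proliferating tissue), a glioblastoma-like class
#' (`gl`, a heterogeneous mix of proliferating and necrotic tissue) and a
#' metastasis-like class (`me`, dominantly necrotic). Each prototype carries
#' the shared constituent-signature matrix and a Dirichlet concentration
#' over the constituents that defines its within-class mixing distribution.
#'
#' @param ppm ppm axis, e.g. [mrs_axis()].
#' @param te_mode `"STE"` or `"LTE"`. STE signatures are element-wise
#'   non-negative; LTE signatures contain the inverted lactate doublet.
#' @return list of class `mrs_prototypes`: one element per class with fields
#'   `name`, `signatures` (d x 2, UL2-normalized columns), `alpha`
#'   (Dirichlet concentration), `mean_spectrum` (UL2-normalized expected
#'   spectrum), plus attributes `ppm` and `te_mode`.
#' @export
make_prototype_sources <- function(ppm = mrs_axis(), te_mode = c("STE", "LTE")) {
  te_mode <- match.arg(te_mode)
  sig <- constituent_signatures(ppm, te_mode)
  alphas <- list(a2 = c(proliferating = 24, necrotic = 1),
                 gl = c(proliferating = 5, necrotic = 5),
                 me = c(proliferating = 1.5, necrotic = 12))
  protos <- lapply(names(alphas), function(nm) {
    a <- alphas[[nm]]
    m <- sig %*% (a / sum(a))
    list(name = nm, signatures = sig, alpha = a,
         mean_spectrum = as.numeric(ul2_normalize(m)))
  })
  names(protos) <- names(alphas)
  structure(protos, ppm = ppm, te_mode = te_mode, class = "mrs_prototypes")
}

#' @export
`[.mrs_prototypes` <- function(x, i) {
  out <- NextMethod()
  attributes(out) <- c(attributes(out),
                       attributes(x)[c("ppm", "te_mode")])
  class(out) <- "mrs_prototypes"
  out
}

rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) { # all-zero draw can only happen with degenerate alpha
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Generate a synthetic SV-MRS dataset with known ground truth
#'
#' Each case is a convex combination of the constituent tissue signatures,
#' with proportions drawn from its class's Dirichlet distribution, plus
#' i.i.d. Gaussian noise, then UL2-normalized (noise enters before
#' normalization, as on real data). `overlap` pulls every class's mixing
#' proportions toward the pooled mean of the other classes, emulating the
#' spectral heterogeneity that makes high-grade tumor types hard to
#' distinguish.
#'
#' @param prototypes output of [make_prototype_sources()], possibly subset.
#' @param n_per_class named integer vector of cohort sizes (names must match
#'   prototype names) or a single count recycled over classes.
#' @param noise_sd standard deviation of the additive Gaussian noise,
#'   relative to unit-norm signatures. Default 0.01.
#' @param overlap in `[0, 1]`; 0 keeps classes at their own mixing
#'   distribution, 1 collapses all classes onto the pooled mean mixing
#'   proportions, so the correlation between class means rises
#'   monotonically with `overlap`.
#' @param seed integer RNG seed.
#' @return list with `dataset` (an `mrs_dataset`) and `truth` (class
#'   `mrs_ground_truth`: `sources` d x k_true constituent signatures,
#'   `proportions` k_true x n column-stochastic mixing matrix, `labels`,
#'   `noise_sd`, `altered` index vector of outlier columns, initially empty).
#' @export
generate_dataset <- function(prototypes, n_per_class, noise_sd = 0.01,
                             overlap = 0, seed = 1L) {
  if (!inherits(prototypes, "mrs_prototypes") || length(prototypes) == 0)
    stop("prototypes must be a non-empty mrs_prototypes list")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  cls <- names(prototypes)
  if (length(n_per_class) == 1 && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, length(cls)), cls)
  if (!all(cls %in% names(n_per_class)))
    stop("n_per_class must name every prototype class")
  if (any(n_per_class < 1)) stop("n_per_class entries must be >= 1")
  ppm <- attr(prototypes, "ppm")
  sig <- prototypes[[1]]$signatures
  k_true <- ncol(sig)

  class_mean_prop <- vapply(prototypes, function(p) p$alpha / sum(p$alpha),
                            numeric(k_true))
  rng <- local_rng(seed)
  on.exit(rng$restore())

  cols <- list(); props <- list(); labels <- character(0)
  pooled <- rowMeans(class_mean_prop)
  for (cl in cls) {
    n_c <- n_per_class[[cl]]
    a <- prototypes[[cl]]$alpha
    pull <- pooled
    for (i in seq_len(n_c)) {
      p <- rdirichlet1(a)
      p <- (1 - overlap) * p + overlap * pull
      p <- p / sum(p)
      x <- as.numeric(sig %*% p)
      if (noise_sd > 0) x <- x + rng$rnorm(length(x), sd = noise_sd)
      cols[[length(cols) + 1L]] <- x
      props[[length(props) + 1L]] <- p
      labels <- c(labels, cl)
    }
  }
  X <- ul2_normalize(do.call(cbind, cols))
  P <- do.call(cbind, props)
  rownames(P) <- colnames(sig)
  ds <- mrs_dataset(X, ppm, labels, attr(prototypes, "te_mode"))
  truth <- structure(list(sources = sig, proportions = P, labels = labels,
                          noise_sd = noise_sd, altered = integer(0)),
                     class = "mrs_ground_truth")
  list(dataset = ds, truth = truth)
}

#' Inject class outliers into a synthetic dataset
#'
#' Replaces the constituent mix of a fraction of one class's cases with the
#' opposite constituent pattern (the mixing proportions reversed), keeping
#' the labels unchanged — cases that read as atypical for their nominal
#' class. The altered column indices are recorded in the ground truth.
#'
#' @param dataset,truth a pair produced by [generate_dataset()].
#' @param class class whose cases are perturbed.
#' @param fraction fraction in `[0, 1)` of that class to alter
#'   (`round(fraction * n_class)` cases).
#' @param seed integer RNG seed.
#' @return list with updated `dataset` and `truth` (`truth$altered` holds the
#'   altered column indices).
#' @export
inject_outliers <- function(dataset, truth, class, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  idx <- which(dataset$labels == class)
  if (length(idx) == 0) stop("class not found: ", class)
  n_alt <- round(fraction * length(idx))
  if (n_alt == 0) return(list(dataset = dataset, truth = truth))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  alt <- sort(rng$sample(idx, n_alt))
  X <- dataset$X
  P <- truth$proportions
  for (j in alt) {
    p_new <- rev(P[, j])
    x <- as.numeric(truth$sources %*% p_new)
    if (truth$noise_sd > 0) x <- x + rng$rnorm(length(x), sd = truth$noise_sd)
    X[, j] <- x / sqrt(sum(x^2))
    P[, j] <- p_new
  }
  ds <- mrs_dataset(X, dataset$ppm, dataset$labels, dataset$te_mode,
                    dataset$case_ids)
  truth$proportions <- P
  truth$altered <- sort(unique(c(truth$altered, alt)))
  list(dataset = ds, truth = truth)
}
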