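#' Chemical-shift axis for single-voxel MRS spectra
#'
#' Builds the ppm axis on which spectra are sampled. The clinical convention
#' plots chemical shift descending from high to low ppm; the default window
#' covers 4.24 to 0.50 ppm with 195 points, the sampling used throughout this
#' package.
#'
#' @param from,to window endpoints in ppm; `from` is the high-field end.
#' @param n number of frequency points (>= 2).
#' @return numeric vector of length `n`, strictly monotone descending.
#' @export
mrs_axis <- function(from = 4.24, to = 0.50, n = 195L) {
  if (n < 2) stop("ppm axis needs at least 2 points")
  if (from == to) stop("ppm axis endpoints must differ")
  ppm <- seq(from, to, length.out = n)
  if (ppm[1] < ppm[n]) ppm <- rev(ppm)
  ppm
}

#' Construct an MRS spectrum dataset
#'
#' The container holds the data matrix in frequencies-by-cases orientation
#' (d x n): each column is one case's spectrum sampled on a shared ppm axis.
#' Labels are optional; unlabeled datasets pass through every unsupervised
#' path but are rejected by posterior-model fitting.
#'
#' @param X numeric matrix, d frequency points x n cases.
#' @param ppm ppm axis, length d, strictly monotone.
#' @param labels optional character vector of per-case class names, length n.
#' @param te_mode echo-time mode, `"STE"` (short) or `"LTE"` (long).
#' @param case_ids optional case identifiers; defaults to colnames or `case_i`.
#' @return an object of class `mrs_dataset`.
#' @export
mrs_dataset <- function(X, ppm, labels = NULL, te_mode = c("STE", "LTE"),
                        case_ids = NULL) {
  te_mode <- match.arg(te_mode)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("spectrum intensities must be finite")
  if (length(ppm) != nrow(X))
    stop("ppm axis length (", length(ppm), ") != matrix rows (", nrow(X), ")")
  dppm <- diff(ppm)
  if (!(all(dppm > 0) || all(dppm < 0))) stop("ppm axis must be strictly monotone")
  n <- ncol(X)
  if (is.null(case_ids)) {
    case_ids <- colnames(X)
    if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(n))
  }
  if (length(case_ids) != n) stop("case_ids length != number of cases")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length (", length(labels),
                                  ") != number of cases (", n, ")")
    if (length(unique(labels)) < 1) stop("label set must be non-empty")
  }
  colnames(X) <- case_ids
  structure(list(X = X, ppm = as.numeric(ppm), labels = labels,
                 te_mode = te_mode, case_ids = case_ids),
            class = "mrs_dataset")
}

#' @export
print.mrs_dataset <- function(x, ...) {
  cat(sprintf("mrs_dataset: %d frequency points x %d cases (%s)\n",
              nrow(x$X), ncol(x$X), x$te_mode))
  cat(sprintf("  ppm window: [%.2f, %.2f]\n", max(x$ppm), min(x$ppm)))
  if (is.null(x$labels)) {
    cat("  unlabeled\n")
  } else {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of cases in a dataset
#' @param dataset an `mrs_dataset`.
#' @return integer case count.
#' @export
n_cases <- function(dataset) ncol(dataset$X)

#' Unit-length (UL2) normalization
#'
#' Scales a spectrum to unit Euclidean norm. For a matrix, each column is
#' normalized independently. UL2 scaling makes spectra acquired with
#' different receiver gains comparable; it is idempotent and invariant to
#' positive rescaling of the input.
#'
#' @param x numeric vector, or matrix with spectra in columns.
#' @return object of the same shape with unit-norm columns.
#' @export
ul2_normalize <- function(x) {
  if (is.matrix(x)) {
    nrm <- sqrt(colSums(x^2))
    if (any(nrm == 0)) stop("cannot UL2-normalize a zero spectrum (column ",
                            paste(which(nrm == 0), collapse = ", "), ")")
    return(sweep(x, 2, nrm, "/"))
  }
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot UL2-normalize a zero spectrum")
  x / nrm
}

#' Mean spectrum of a class
#'
#' Arithmetic mean over the columns carrying the given label. Class means are
#' the reference patterns against which extracted sources are interpreted.
#'
#' @param dataset a labeled `mrs_dataset`.
#' @param class class name present in the labels.
#' @return numeric vector of length d.
#' @export
class_mean_spectrum <- function(dataset, class) {
  if (is.null(dataset$labels)) stop("dataset is unlabeled")
  idx <- which(dataset$labels == class)
  if (length(idx) == 0) stop("class not found: ", class)
  rowMeans(dataset$X[, idx, drop = FALSE])
}

#' All class mean spectra
#' @param dataset a labeled `mrs_dataset`.
#' @return d x C matrix, one column per class (sorted class names).
#' @export
class_means <- function(dataset) {
  if (is.null(dataset$labels)) stop("dataset is unlabeled")
  cls <- sort(unique(dataset$labels))
  M <- vapply(cls, function(cl) class_mean_spectrum(dataset, cl),
              numeric(nrow(dataset$X)))
  colnames(M) <- cls
  M
}

#' Subset a dataset by case index
#' @param dataset an `mrs_dataset`.
#' @param idx integer or logical index over cases.
#' @return an `mrs_dataset` with the selected cases.
#' @export
subset_cases <- function(dataset, idx) {
  mrs_dataset(dataset$X[, idx, drop = FALSE], dataset$ppm,
              labels = if (is.null(dataset$labels)) NULL else dataset$labels[idx],
              te_mode = dataset$te_mode,
              case_ids = dataset$case_ids[idx])
}

#' Subset a dataset to a set of classes, optionally merging into superclasses
#'
#' `keep` selects classes; `superclass` merges member classes under one name,
#' e.g. `list(AG = c("GL", "ME"))` builds the aggressive superclass used for
#' grade II vs grade IV discrimination.
#'
#' @param dataset a labeled `mrs_dataset`.
#' @param keep character vector of class names to retain (after merging).
#' @param superclass named list mapping superclass name to member classes.
#' @return an `mrs_dataset`.
#' @export
select_classes <- function(dataset, keep = NULL, superclass = NULL) {
  if (is.null(dataset$labels)) stop("dataset is unlabeled")
  labels <- dataset$labels
  if (!is.null(superclass)) {
    members <- unlist(superclass)
    if (anyDuplicated(members)) stop("superclass member sets must be disjoint")
    for (sc in names(superclass)) {
      labels[labels %in% superclass[[sc]]] <- sc
    }
  }
  ds <- mrs_dataset(dataset$X, dataset$ppm, labels, dataset$te_mode,
                    dataset$case_ids)
  if (!is.null(keep)) {
    missing <- setdiff(keep, unique(labels))
    if (length(missing)) stop("class not found: ", paste(missing, collapse = ", "))
    ds <- subset_cases(ds, labels %in% keep)
  }
  ds
}

#' Stratified train/holdout split
#'
#' Splits cases into disjoint, exhaustive train and holdout sets, stratified
#' by class. Per class the train size is `round(fraction * n_class)`; the
#' remainder goes to the holdout. A class with fewer than 2 members cannot be
#' stratified and is kept entirely in the training set (with a warning).
#'
#' @param dataset a labeled `mrs_dataset` with at least 3 cases.
#' @param fraction training fraction, strictly inside (0, 1). Default 2/3.
#' @param seed integer RNG seed; identical seeds give identical splits.
#' @return list with elements `train` and `holdout`, both `mrs_dataset`s, and
#'   `train_idx`/`holdout_idx` giving the original column indices.
#' @export
split_dataset <- function(dataset, fraction = 2 / 3, seed = 1L) {
  if (is.null(dataset$labels)) stop("split_dataset requires labels")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- n_cases(dataset)
  if (n < 3) stop("need at least 3 cases to split")
  rng <- local_rng(seed)
  train_idx <- integer(0)
  for (cl in sort(unique(dataset$labels))) {
    idx <- which(dataset$labels == cl)
    if (length(idx) < 2) {
      warning("class '", cl, "' has < 2 members; kept entirely in train")
      train_idx <- c(train_idx, idx)
      next
    }
    n_tr <- round(fraction * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train_idx <- c(train_idx, rng$sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  holdout_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_cases(dataset, train_idx),
       holdout = subset_cases(dataset, holdout_idx),
       train_idx = train_idx, holdout_idx = holdout_idx)
}

#' Read an MRS dataset from a delimited table
#'
#' Two orientations are supported. `cases-rows` (the common spreadsheet
#' export): one row per case, columns named by their ppm values, with
#' optional `case_id` and `label` columns. `cases-cols`: one column per case,
#' first column `ppm`, with an optional leading row whose ppm cell reads
#' `label` carrying the class names.
#'
#' @param path file path; tab- or comma-delimited inferred from extension.
#' @param orientation `"cases-rows"` (default) or `"cases-cols"`.
#' @param te_mode echo-time mode tag to attach.
#' @param sep field separator; default inferred (`,` for `.csv`, else tab).
#' @return an `mrs_dataset`.
#' @export
read_mrs <- function(path, orientation = c("cases-rows", "cases-cols"),
                     te_mode = c("STE", "LTE"), sep = NULL) {
  orientation <- match.arg(orientation)
  te_mode <- match.arg(te_mode)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, fill = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop("malformed table in ", path, ": ",
                             conditionMessage(e)))
  if (orientation == "cases-rows") {
    labels <- NULL
    case_ids <- NULL
    if ("label" %in% names(raw)) {
      labels <- as.character(raw[["label"]])
      raw[["label"]] <- NULL
    }
    if ("case_id" %in% names(raw)) {
      case_ids <- as.character(raw[["case_id"]])
      raw[["case_id"]] <- NULL
    }
    ppm <- suppressWarnings(as.numeric(names(raw)))
    if (anyNA(ppm)) stop("non-numeric ppm header column(s): ",
                         paste(names(raw)[is.na(ppm)], collapse = ", "))
    X <- t(as.matrix(parse_numeric_frame(raw, path)))
    mrs_dataset(X, ppm, labels, te_mode, case_ids)
  } else {
    if (!identical(names(raw)[1], "ppm"))
      stop("cases-cols orientation requires a leading 'ppm' column")
    labels <- NULL
    if (nrow(raw) > 0 && identical(as.character(raw[1, 1]), "label")) {
      labels <- as.character(unlist(raw[1, -1]))
      raw <- raw[-1, , drop = FALSE]
    }
    ppm <- suppressWarnings(as.numeric(raw[[1]]))
    if (anyNA(ppm)) stop("non-numeric ppm value at row ",
                         paste(which(is.na(ppm)), collapse = ", "))
    X <- as.matrix(parse_numeric_frame(raw[, -1, drop = FALSE], path))
    mrs_dataset(X, ppm, labels, te_mode, case_ids = names(raw)[-1])
  }
}

parse_numeric_frame <- function(df, path) {
  out <- vapply(seq_along(df), function(j) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) && !all(is.na(df[[j]])))
      stop("non-numeric cell in ", path, " at column ", names(df)[j],
           ", row ", which(is.na(v))[1])
    v
  }, numeric(nrow(df)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(df))
  out
}

#' Write an MRS dataset to a delimited table
#'
#' Inverse of [read_mrs()]; round-trips intensities to full double precision
#' and labels exactly.
#'
#' @param dataset an `mrs_dataset`.
#' @param path output path.
#' @param orientation as in [read_mrs()].
#' @param sep field separator; default inferred from extension.
#' @export
write_mrs <- function(dataset, path,
                      orientation = c("cases-rows", "cases-cols"), sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  ppm_h <- format(dataset$ppm, digits = 17, trim = TRUE, scientific = FALSE)
  if (orientation == "cases-rows") {
    df <- as.data.frame(t(dataset$X))
    names(df) <- ppm_h
    df <- cbind(case_id = dataset$case_ids, df, stringsAsFactors = FALSE)
    if (!is.null(dataset$labels)) df$label <- dataset$labels
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    header <- c("ppm", dataset$case_ids)
    lines <- paste(header, collapse = sep)
    if (!is.null(dataset$labels))
      lines <- c(lines, paste(c("label", dataset$labels), collapse = sep))
    body <- vapply(seq_len(nrow(dataset$X)), function(i) {
      paste(c(ppm_h[i], format(dataset$X[i, ], digits = 17, trim = TRUE)),
            collapse = sep)
    }, character(1))
    writeLines(c(lines, body), path, useBytes = TRUE)
  }
  invisible(path)
}
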