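#' Back-project an unmixing matrix to spectral sources
#'
#' The Convex-NMF unmixing matrix W expresses each source as a non-negative
#' combination of cases, so applying it to the original spectra — even when
#' the factorization ran in a latent embedded space — yields sources that
#' display as spectra on the ppm axis. Columns are UL2-normalized for
#' display and correlation against class means.
#'
#' @param W n x k unmixing matrix from a fitted model on the same n cases.
#' @param X_original d x n matrix of the original spectra.
#' @return d x k matrix of unit-norm spectral sources.
#' @export
backproject_sources <- function(W, X_original) {
  if (ncol(X_original) != nrow(W))
    stop("W rows (", nrow(W), ") must match cases (", ncol(X_original), ")")
  S <- X_original %*% W
  nrm <- sqrt(colSums(S^2))
  nrm[nrm == 0] <- 1
  sweep(S, 2, nrm, "/")
}

#' Assign extracted sources to tumor classes by correlation
#'
#' Computes Pearson correlations between every source and every class mean
#' spectrum (both UL2-normalized) and picks the assignment of sources to
#' classes that maximizes the total matched correlation, under the
#' constraint that every class receives at least one source whenever
#' k >= C. The matching is found by exhaustive enumeration (k <= 6 always
#' holds here), so it is exactly optimal. A source whose best correlation is
#' negative — a sign indeterminacy inherited from the latent space — is
#' sign-flipped before matching and the flip recorded. A zero-variance
#' source has no defined correlation and is assigned by smallest Euclidean
#' distance instead, flagged in `fallback`.
#'
#' @param spectral_sources d x k matrix of sources (e.g. from
#'   [backproject_sources()]).
#' @param class_means d x C matrix of class mean spectra, columns named by
#'   class.
#' @return object of class `source_assignment`: `class_of_source` (length-k
#'   character), `correlations` (k x C), `matched_correlation` (per source,
#'   against its assigned class), `flipped`, `fallback`, and the possibly
#'   sign-corrected `sources`.
#' @export
assign_sources_to_classes <- function(spectral_sources, class_means) {
  S <- as.matrix(spectral_sources)
  M <- ul2_normalize(as.matrix(class_means))
  k <- ncol(S); C <- ncol(M)
  if (k < 1 || C < 2) stop("need k >= 1 sources and C >= 2 classes")
  classes <- colnames(M)
  if (is.null(classes)) stop("class_means must have named columns")
  cor1 <- function(s, m) {
    if (stats::sd(s) == 0 || stats::sd(m) == 0) return(NA_real_)
    stats::cor(s, m)
  }
  R <- matrix(NA_real_, k, C, dimnames = list(NULL, classes))
  fallback <- logical(k)
  flipped <- logical(k)
  for (j in seq_len(k)) {
    r <- vapply(seq_len(C), function(c) cor1(S[, j], M[, c]), numeric(1))
    if (all(is.na(r))) {
      fallback[j] <- TRUE
      dist_c <- vapply(seq_len(C), function(c) sqrt(sum((S[, j] - M[, c])^2)),
                       numeric(1))
      r <- -dist_c            # surrogate score: closer is better
    } else if (max(r, na.rm = TRUE) < 0) {
      S[, j] <- -S[, j]
      flipped[j] <- TRUE
      r <- -r
    }
    R[j, ] <- r
  }
  # exhaustive optimal matching over class assignments
  grids <- rep(list(seq_len(C)), k)
  combos <- as.matrix(expand.grid(grids))
  if (k >= C) {
    covers <- apply(combos, 1, function(a) length(unique(a)) == C)
    combos <- combos[covers, , drop = FALSE]
  }
  scores <- apply(combos, 1, function(a) sum(R[cbind(seq_len(k), a)]))
  best <- combos[which.max(scores), ]
  structure(list(class_of_source = classes[best],
                 correlations = R,
                 matched_correlation = R[cbind(seq_len(k), best)],
                 flipped = flipped, fallback = fallback, sources = S),
            class = "source_assignment")
}

#' Label cases from the mixing matrix
#'
#' Each case takes the class of the source with the highest value in its
#' column of the (rescaled) mixing matrix. Ties break to the lowest source
#' index. An all-zero column cannot be attributed and is labeled with
#' `fallback_class` (default the first assigned class) and flagged.
#'
#' @param H k x m mixing matrix, rescaled via [rescale_sources()].
#' @param assignment a `source_assignment` covering all k sources.
#' @param fallback_class class used for all-zero columns; default the most
#'   frequent class in the assignment.
#' @return object of class `labeling_result`: `predicted` labels,
#'   `source_argmax` winning source per case, `H_used`, `undetermined`
#'   flags.
#' @export
label_cases <- function(H, assignment, fallback_class = NULL) {
  stopifnot(inherits(assignment, "source_assignment"))
  H <- as.matrix(H)
  if (nrow(H) != length(assignment$class_of_source))
    stop("H rows must equal number of assigned sources")
  if (is.null(fallback_class)) {
    tab <- table(assignment$class_of_source)
    fallback_class <- names(tab)[which.max(tab)]
  }
  winner <- apply(H, 2, which.max)       # ties -> lowest index
  undetermined <- colSums(H != 0) == 0
  predicted <- assignment$class_of_source[winner]
  predicted[undetermined] <- fallback_class
  structure(list(predicted = predicted, source_argmax = winner,
                 H_used = H, undetermined = undetermined),
            class = "labeling_result")
}

summarize_counts <- function(correct, total) {
  stopifnot(length(correct) == length(total), all(correct <= total))
  per_class_accuracy <- 100 * correct / total
  list(total_accuracy = 100 * sum(correct) / sum(total),
       per_class_accuracy = per_class_accuracy,
       correct_counts = cbind(correct = correct, total = total),
       ber = mean(1 - per_class_accuracy / 100))
}

#' Score predicted labels against the truth
#'
#' Reports per-class correct counts and accuracies, total accuracy, and the
#' balanced error rate (BER) — the mean of the per-class error rates, which
#' unlike total accuracy is insensitive to class imbalance.
#'
#' @param predicted character vector of predicted class labels.
#' @param truth character vector of true labels, same length.
#' @return object of class `eval_report`: `total_accuracy` (percent),
#'   `per_class_accuracy` (percent, named), `correct_counts` (correct/total
#'   per class), `ber` in `[0, 1]`.
#' @export
evaluate_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  classes <- sort(unique(truth))
  bad <- setdiff(unique(predicted), classes)
  if (length(bad))
    stop("predicted class not in truth set: ", paste(bad, collapse = ", "))
  correct <- vapply(classes, function(cl)
    sum(predicted == cl & truth == cl), numeric(1))
  total <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  out <- summarize_counts(correct, total)
  names(out$per_class_accuracy) <- classes
  rownames(out$correct_counts) <- classes
  structure(out, class = "eval_report")
}

#' Evaluation arithmetic from per-class counts
#'
#' Recomputes total accuracy and BER directly from per-class
#' (correct, total) counts — the arithmetic used in published accuracy
#' tables of the form "88.0% (95/108)".
#'
#' @param correct,total integer vectors of per-class correct and total
#'   counts.
#' @return an `eval_report` (without named classes).
#' @export
evaluate_counts <- function(correct, total) {
  structure(summarize_counts(correct, total), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cc <- x$correct_counts
  cat(sprintf("Total  %s\n", format_accuracy(sum(cc[, 1]), sum(cc[, 2]))))
  cls <- rownames(cc)
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("%-6s %s\n", if (is.null(cls)) paste0("class", i) else cls[i],
                format_accuracy(cc[i, 1], cc[i, 2])))
  }
  cat(sprintf("BER    %.3f\n", x$ber))
  invisible(x)
}

#' Format an accuracy cell as "percent% (correct/total)"
#'
#' @param correct,total counts.
#' @return character scalar, e.g. `"88.0% (95/108)"`.
#' @export
format_accuracy <- function(correct, total) {
  sprintf("%.1f%% (%d/%d)", 100 * correct / total, as.integer(correct),
          as.integer(total))
}
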