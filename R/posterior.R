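#' Fit a neural class-posterior model
#'
#' Trains a single-hidden-layer feed-forward network (tanh hidden units,
#' softmax output) to estimate the conditional class-membership
#' probabilities p(c|x) of labeled spectra. The smooth architecture is
#' deliberate: the Fisher Information metric needs analytic, well-behaved
#' gradients of the log-posteriors with respect to the input, which
#' [posterior_log_gradient()] computes by backpropagation to the input
#' layer.
#'
#' Optimization is deterministic full-batch gradient descent on the
#' cross-entropy plus L2 weight decay, with an adaptive step (growth on
#' acceptance, halving on rejection), so the training-loss trace is
#' non-increasing by construction. The seed controls only the weight
#' initialization. The holdout set monitors generalization: the returned
#' weights are those with the best holdout loss seen during training.
#'
#' @param train labeled `mrs_dataset` with at least 2 classes.
#' @param holdout labeled `mrs_dataset` sharing the training classes; used
#'   for early stopping and the reported holdout accuracy.
#' @param hidden number of hidden units. Default 8.
#' @param decay L2 weight-decay coefficient on the weights (not the biases).
#'   Default 1e-3.
#' @param max_epochs epoch budget. Default 400.
#' @param patience epochs without holdout-loss improvement before stopping.
#' @param seed integer seed for weight initialization.
#' @return object of class `posterior_model`: weights `W1` (h x d), `b1`,
#'   `W2` (C x h), `b2`, the sorted `classes`, the training `loss_trace`,
#'   and metadata (`holdout_accuracy`, `seed`, `epochs_run`).
#' @export
fit_posterior <- function(train, holdout, hidden = 8L, decay = 1e-3,
                          max_epochs = 400L, patience = 50L, seed = 1L) {
  if (is.null(train$labels)) stop("training data must be labeled")
  classes <- sort(unique(train$labels))
  if (length(classes) < 2) stop("need at least 2 classes to fit a posterior")
  if (is.null(holdout$labels) || !all(holdout$labels %in% classes))
    stop("holdout must be labeled with training classes")
  X <- train$X; d <- nrow(X); n <- ncol(X); C <- length(classes)
  Y <- outer(train$labels, classes, "==") * 1           # n x C one-hot
  rng <- local_rng(seed)
  on.exit(rng$restore())
  theta <- list(W1 = matrix(rng$rnorm(hidden * d, sd = 0.1), hidden, d),
                b1 = numeric(hidden),
                W2 = matrix(rng$rnorm(C * hidden, sd = 0.1), C, hidden),
                b2 = numeric(C))

  forward <- function(th, X) {
    Z <- tanh(th$W1 %*% X + th$b1)                      # h x n
    A <- th$W2 %*% Z + th$b2                            # C x n
    A <- sweep(A, 2, apply(A, 2, max), "-")
    P <- exp(A); P <- sweep(P, 2, colSums(P), "/")
    list(Z = Z, P = P)
  }
  loss_of <- function(th, X, Y) {
    P <- forward(th, X)$P
    -mean(log(pmax(colSums(t(Y) * P), 1e-300))) +
      decay * 0.5 * (sum(th$W1^2) + sum(th$W2^2))
  }
  grad_of <- function(th, fw) {
    Delta <- (fw$P - t(Y)) / n                          # C x n
    gW2 <- Delta %*% t(fw$Z) + decay * th$W2
    gb2 <- rowSums(Delta)
    Dz <- (t(th$W2) %*% Delta) * (1 - fw$Z^2)           # h x n
    gW1 <- Dz %*% t(X) + decay * th$W1
    gb1 <- rowSums(Dz)
    list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }

  step <- 0.5
  loss <- loss_of(theta, X, Y)
  trace <- loss
  best <- list(theta = theta,
               hloss = loss_of(theta, holdout$X,
                               outer(holdout$labels, classes, "==") * 1),
               epoch = 0L)
  Yh <- outer(holdout$labels, classes, "==") * 1
  stall <- 0L
  epochs_run <- 0L
  for (ep in seq_len(max_epochs)) {
    fw <- forward(theta, X)
    g <- grad_of(theta, fw)
    accepted <- FALSE
    while (step > 1e-12) {
      cand <- list(W1 = theta$W1 - step * g$W1, b1 = theta$b1 - step * g$b1,
                   W2 = theta$W2 - step * g$W2, b2 = theta$b2 - step * g$b2)
      cand_loss <- loss_of(cand, X, Y)
      if (is.finite(cand_loss) && cand_loss <= loss) {
        theta <- cand; loss <- cand_loss; step <- step * 1.2
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    epochs_run <- ep
    if (!accepted) break
    trace <- c(trace, loss)
    hloss <- loss_of(theta, holdout$X, Yh)
    if (!is.finite(loss)) stop("non-finite training loss at epoch ", ep)
    if (hloss < best$hloss - 1e-12) {
      best <- list(theta = theta, hloss = hloss, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  theta <- best$theta
  model <- structure(c(theta, list(classes = classes, decay = decay,
                                   loss_trace = trace, seed = seed,
                                   epochs_run = epochs_run)),
                     class = "posterior_model")
  pred <- predict_posterior(model, holdout$X)
  model$holdout_accuracy <-
    mean(classes[apply(pred, 2, which.max)] == holdout$labels) * 100
  model
}

#' Class-membership probabilities
#'
#' @param model a `posterior_model`.
#' @param x spectrum vector of length d, or a d x m matrix of spectra in
#'   columns.
#' @return C x m matrix of probabilities (rows named by class); columns sum
#'   to 1.
#' @export
predict_posterior <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(X) != ncol(model$W1))
    stop("input dimension ", nrow(X), " != model input size ", ncol(model$W1))
  Z <- tanh(model$W1 %*% X + model$b1)
  A <- model$W2 %*% Z + model$b2
  A <- sweep(A, 2, apply(A, 2, max), "-")
  P <- exp(A)
  P <- sweep(P, 2, colSums(P), "/")
  rownames(P) <- model$classes
  P
}

#' Input-space gradients of the log-posteriors
#'
#' Exact analytic gradients of log p(c|x) with respect to the input x, for
#' every class c, obtained by backpropagating through the network. These are
#' the raw material of the Fisher Information metric. The normalization
#' identity sum_c p(c|x) grad log p(c|x) = 0 holds exactly.
#'
#' @param model a `posterior_model`.
#' @param x spectrum vector of length d.
#' @return C x d matrix; row c is grad_x log p(c|x).
#' @export
posterior_log_gradient <- function(model, x) {
  if (length(x) != ncol(model$W1))
    stop("input dimension ", length(x), " != model input size ",
         ncol(model$W1))
  z <- tanh(as.numeric(model$W1 %*% x + model$b1))
  a <- as.numeric(model$W2 %*% z + model$b2)
  a <- a - max(a)
  p <- exp(a); p <- p / sum(p)
  C <- length(p)
  # d log p_c / da = e_c - p ; da/dz = W2 ; dz/dx = diag(1 - z^2) W1
  M <- (diag(C) - matrix(p, C, C, byrow = TRUE)) %*%
    (model$W2 * rep(1 - z^2, each = C)) %*% model$W1
  rownames(M) <- model$classes
  M
}
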