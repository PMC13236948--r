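#' Row-wise softmax
#'
#' Numerically stable softmax (max-subtraction guard). Accepts a vector or a
#' matrix of logits; the transform is invariant to adding a constant to a
#' row.
#'
#' @param logits Numeric vector or matrix (rows = samples).
#' @return Probability vector or matrix of the same shape; rows sum to 1.
#' @examples
#' softmax(c(log(2), 0))
#' @export
softmax <- function(logits) {
  if (is.vector(logits)) {
    if (any(!is.finite(logits))) stop("logits must be finite", call. = FALSE)
    z <- logits - max(logits)
    e <- exp(z)
    return(e / sum(e))
  }
  if (any(!is.finite(logits))) stop("logits must be finite", call. = FALSE)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Mean multiclass cross-entropy
#'
#' Mean over samples of the negative log-probability assigned to the true
#' class. Zero probabilities are clamped at `eps` with a warning, since the
#' loss is otherwise infinite.
#'
#' @param probabilities Matrix with simplex-valued rows.
#' @param labels Integer labels, 0-based, in `[0, K)`.
#' @param eps Clamp for zero true-class probabilities (default 1e-12).
#' @return Non-negative scalar.
#' @examples
#' cross_entropy(matrix(c(0.7, 0.3), 1), 0L)  # -log(0.7)
#' @export
cross_entropy <- function(probabilities, labels, eps = 1e-12) {
  assert_prob_matrix(probabilities)
  labels <- assert_labels(labels, nrow(probabilities), ncol(probabilities))
  p_true <- probabilities[cbind(seq_len(nrow(probabilities)), labels + 1L)]
  if (any(p_true <= 0)) {
    warning("true-class probabilities of 0 clamped at eps")
    p_true <- pmax(p_true, eps)
  }
  -mean(log(p_true))
}

#' Hyper-parameters for linear-head training
#'
#' Full-batch gradient descent on the multiclass cross-entropy with weight
#' decay. Validation accuracy is checked every `check_every` steps and the
#' best checkpoint is retained; training stops early after `patience`
#' consecutive checks without improvement.
#'
#' @param learning_rate Step size for full-batch gradient descent.
#' @param steps Maximum number of full-batch steps.
#' @param weight_decay L2 penalty on the weights (not the bias).
#' @param patience Early-stopping patience, counted in validation checks.
#' @param check_every Steps between validation checks.
#' @return A named list of class `head_hyper`.
#' @export
head_hyper <- function(learning_rate = 1.0, steps = 600L,
                       weight_decay = 1e-3, patience = 8L,
                       check_every = 25L) {
  structure(list(learning_rate = learning_rate, steps = as.integer(steps),
                 weight_decay = weight_decay, patience = as.integer(patience),
                 check_every = as.integer(check_every)),
            class = "head_hyper")
}

#' Train a linear classification head on frozen features
#'
#' Fits weights `W` (d x K) and bias `b` by full-batch gradient descent on
#' the mean cross-entropy plus an L2 weight penalty, retaining the checkpoint
#' with the highest validation accuracy. Training is deterministic given the
#' data, hyper-parameters, and seed.
#'
#' @param train_features,train_labels Training matrix (n x d) and 0-based
#'   integer labels.
#' @param val_features,val_labels Validation split used for early stopping
#'   and checkpoint selection.
#' @param n_classes Number of classes K; defaults to `max(label) + 1`.
#' @param hyper A [head_hyper()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `linear_head`: list with `weights`, `bias`,
#'   `seed`, `n_classes`, and `training_log` (tibble of step /
#'   validation-accuracy pairs).
#' @export
train_linear_head <- function(train_features, train_labels,
                              val_features, val_labels,
                              n_classes = NULL, hyper = head_hyper(),
                              seed = 1L) {
  X <- as.matrix(train_features)
  Xv <- as.matrix(val_features)
  if (ncol(X) != ncol(Xv)) stop("feature dimensions differ", call. = FALSE)
  K <- as.integer(n_classes %||% (max(train_labels, val_labels) + 1L))
  if (K < 2L || length(unique(train_labels)) < 2L) {
    stop("need >= 2 classes in training data", call. = FALSE)
  }
  y <- assert_labels(train_labels, nrow(X), K)
  yv <- assert_labels(val_labels, nrow(Xv), K)
  n <- nrow(X)
  d <- ncol(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y + 1L)] <- 1

  with_seed(seed, {
    W <- matrix(stats::rnorm(d * K, sd = 0.01), d, K)
    b <- numeric(K)
    best <- list(W = W, b = b, acc = -Inf, step = 0L)
    log_rows <- list()
    stale <- 0L
    for (step in seq_len(hyper$steps)) {
      P <- softmax(sweep(X %*% W, 2, b, "+"))
      G <- (P - Y) / n
      gW <- crossprod(X, G) + hyper$weight_decay * W
      gb <- colSums(G)
      if (any(!is.finite(gW)) || any(!is.finite(gb))) {
        stop("non-finite loss encountered during head training",
             call. = FALSE)
      }
      W <- W - hyper$learning_rate * gW
      b <- b - hyper$learning_rate * gb
      if (step %% hyper$check_every == 0L || step == hyper$steps) {
        pred <- max.col(sweep(Xv %*% W, 2, b, "+"), ties.method = "first") - 1L
        acc <- mean(pred == yv)
        log_rows[[length(log_rows) + 1L]] <-
          tibble::tibble(step = step, val_accuracy = acc)
        if (acc > best$acc) {
          best <- list(W = W, b = b, acc = acc, step = step)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= hyper$patience) break
        }
      }
    }
    structure(
      list(weights = best$W, bias = best$b, seed = as.integer(seed),
           n_classes = K, best_val_accuracy = best$acc,
           training_log = dplyr::bind_rows(log_rows)),
      class = "linear_head"
    )
  })
}

#' @export
print.linear_head <- function(x, ...) {
  cat(sprintf("<linear_head> %d features -> %d classes (seed %d, best val acc %.3f)\n",
              nrow(x$weights), x$n_classes, x$seed, x$best_val_accuracy))
  invisible(x)
}

#' Logits of a linear head on a feature matrix
#'
#' @param head A [train_linear_head()] result.
#' @param features Numeric matrix (n x d).
#' @return Numeric logit matrix (n x K).
#' @export
head_logits <- function(head, features) {
  stopifnot(inherits(head, "linear_head"))
  sweep(as.matrix(features) %*% head$weights, 2, head$bias, "+")
}

#' Channel-wise feature statistics
#'
#' Per-dimension mean and standard deviation (n - 1 normalization), the
#' sufficient statistics for diagonal moment matching.
#'
#' @param features Numeric matrix with >= 2 rows.
#' @return An object of class `channel_stats`: list with `mean` and `std`
#'   vectors of length `ncol(features)`.
#' @export
channel_stats <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need >= 2 rows", call. = FALSE)
  structure(
    list(mean = colMeans(features), std = apply(features, 2, stats::sd)),
    class = "channel_stats"
  )
}

#' Diagonal feature moment matching
#'
#' Affine-aligns source features to target channel statistics:
#' `h_aligned = sigma_t * (h - mu_s) / sigma_s + mu_t`, applied per channel.
#' Channels whose source standard deviation falls below `eps` are rescaled
#' with `eps` instead and flagged with a warning.
#'
#' @param source_features Numeric matrix to align.
#' @param source_stats,target_stats [channel_stats()] of the source and
#'   target domains.
#' @param eps Lower clamp for the source standard deviation (default 1e-12).
#' @return Aligned matrix with the same shape as `source_features`.
#' @export
moment_match <- function(source_features, source_stats, target_stats,
                         eps = 1e-12) {
  stopifnot(inherits(source_stats, "channel_stats"),
            inherits(target_stats, "channel_stats"))
  X <- as.matrix(source_features)
  d <- ncol(X)
  if (length(source_stats$mean) != d || length(target_stats$mean) != d) {
    stop("statistic dimensions do not match the features", call. = FALSE)
  }
  s_s <- source_stats$std
  if (any(s_s < eps)) {
    warning("source std below eps in some channels; clamped")
    s_s <- pmax(s_s, eps)
  }
  Xc <- sweep(X, 2, source_stats$mean, "-")
  Xc <- sweep(Xc, 2, target_stats$std / s_s, "*")
  sweep(Xc, 2, target_stats$mean, "+")
}

#' Train an ensemble of linear heads differing only in initialization seed
#'
#' @inheritParams train_linear_head
#' @param seeds Integer vector of member seeds (length M >= 2). Duplicate
#'   seeds trigger a warning, since the corresponding members coincide
#'   exactly under the deterministic trainer.
#' @return List of `linear_head` objects, one per seed.
#' @export
train_head_ensemble <- function(train_features, train_labels,
                                val_features, val_labels,
                                n_classes = NULL, hyper = head_hyper(),
                                seeds = 1:5) {
  if (length(seeds) < 2) stop("need >= 2 member seeds", call. = FALSE)
  if (anyDuplicated(seeds)) {
    warning("duplicate seeds: the corresponding ensemble members coincide")
  }
  lapply(seeds, function(s) {
    train_linear_head(train_features, train_labels, val_features, val_labels,
                      n_classes = n_classes, hyper = hyper, seed = s)
  })
}
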