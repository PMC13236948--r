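#' Bundle member probabilities into an ensemble batch
#'
#' @param member_probabilities List of M probability matrices (n x K) with
#'   simplex-valued rows, or a 3-way array `M x n x K`.
#' @param member_seeds Optional integer vector of member seeds (audit only).
#' @return An object of class `ensemble_batch`: list with `probs` (3-way
#'   array `M x n x K`) and `member_seeds`.
#' @export
ensemble_batch <- function(member_probabilities, member_seeds = NULL) {
  if (is.list(member_probabilities)) {
    M <- length(member_probabilities)
    if (M < 2) stop("need M >= 2 members", call. = FALSE)
    dims <- dim(member_probabilities[[1]])
    arr <- array(NA_real_, c(M, dims[1], dims[2]))
    for (m in seq_len(M)) {
      p <- as.matrix(member_probabilities[[m]])
      if (!all(dim(p) == dims)) stop("member shapes differ", call. = FALSE)
      assert_prob_matrix(p, sprintf("member %d", m))
      arr[m, , ] <- p
    }
  } else {
    arr <- member_probabilities
    if (length(dim(arr)) != 3 || dim(arr)[1] < 2) {
      stop("need an M x n x K array with M >= 2", call. = FALSE)
    }
    for (m in seq_len(dim(arr)[1])) {
      assert_prob_matrix(matrix(arr[m, , ], dim(arr)[2], dim(arr)[3]),
                         sprintf("member %d", m))
    }
  }
  structure(list(probs = arr, member_seeds = member_seeds),
            class = "ensemble_batch")
}

#' Ensemble predictive distribution
#'
#' Arithmetic mean of the member softmax outputs; rows remain simplex-valued.
#'
#' @param batch An [ensemble_batch()].
#' @return Probability matrix (n x K).
#' @export
ensemble_mean <- function(batch) {
  stopifnot(inherits(batch, "ensemble_batch"))
  apply(batch$probs, c(2, 3), mean)
}

#' Epistemic-aleatoric uncertainty decomposition
#'
#' Per sample (natural log): predictive entropy of the ensemble mean (total
#' uncertainty), mean member entropy (aleatoric proxy), and their difference,
#' the mutual information between the prediction and the member index
#' (epistemic proxy). The additive identity
#' `predictive_entropy = aleatoric + epistemic_mi` holds to floating-point
#' accuracy and `epistemic_mi >= 0` by Jensen's inequality; zero member rows
#' follow the `0 log 0 = 0` convention.
#'
#' @param batch An [ensemble_batch()].
#' @return A tibble with columns `predictive_entropy`, `aleatoric`,
#'   `epistemic_mi` (one row per sample).
#' @export
decompose_uncertainty <- function(batch) {
  stopifnot(inherits(batch, "ensemble_batch"))
  M <- dim(batch$probs)[1]
  n <- dim(batch$probs)[2]
  p_bar <- ensemble_mean(batch)
  h_bar <- apply(p_bar, 1, entropy_nat)
  h_members <- matrix(NA_real_, M, n)
  for (m in seq_len(M)) {
    pm <- matrix(batch$probs[m, , ], n, dim(batch$probs)[3])
    h_members[m, ] <- apply(pm, 1, entropy_nat)
  }
  aleatoric <- colMeans(h_members)
  tibble::tibble(
    predictive_entropy = h_bar,
    aleatoric = aleatoric,
    epistemic_mi = h_bar - aleatoric
  )
}

#' Ensemble predictive logits
#'
#' Elementwise natural log of the mean probabilities - the unique logit
#' definition whose T = 1 softmax reproduces the ensemble predictive
#' distribution, which makes temperature scaling applicable to the ensemble
#' path. Zero entries are clamped at `eps` with a warning.
#'
#' @param mean_probabilities Probability matrix from [ensemble_mean()].
#' @param eps Clamp for zero probabilities (default 1e-12).
#' @return Logit matrix of the same shape.
#' @export
ensemble_predictive_logits <- function(mean_probabilities, eps = 1e-12) {
  assert_prob_matrix(mean_probabilities, "mean_probabilities")
  p <- mean_probabilities
  if (any(p <= 0)) {
    warning("zero mean probabilities clamped at eps before log")
    p <- pmax(p, eps)
  }
  log(p)
}

#' Member probabilities of a head ensemble on a feature matrix
#'
#' Convenience wrapper: applies each linear head, optionally
#' temperature-scales per member, and bundles the softmax outputs.
#'
#' @param heads List of `linear_head` objects.
#' @param features Feature matrix.
#' @param T Temperature applied to every member (default 1).
#' @return An [ensemble_batch()].
#' @export
ensemble_member_probs <- function(heads, features, T = 1) {
  probs <- lapply(heads, function(h) {
    apply_temperature(head_logits(h, features), T)
  })
  ensemble_batch(probs, member_seeds = vapply(heads, `[[`, integer(1),
                                              "seed"))
}
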