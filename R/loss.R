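#' Row-wise softmax
#'
#' Applies a numerically stable (max-shifted) softmax to every row of a
#' score matrix, turning each row into the class distribution of one L-class
#' classification.
#'
#' @param Mhat a numeric matrix with finite entries.
#' @return A matrix of the same shape whose rows sum to 1.
#' @export
row_softmax <- function(Mhat) {
  if (!all(is.finite(Mhat)))
    stop("score matrix must be finite", call. = FALSE)
  E <- exp(Mhat - apply(Mhat, 1L, max))
  E / rowSums(E)
}

# row-wise log-softmax, used internally so the loss never takes log(0)
row_log_softmax <- function(Mhat) {
  m <- apply(Mhat, 1L, max)
  Z <- Mhat - m
  Z - log(rowSums(exp(Z)))
}

as_matrix_batch <- function(x) {
  if (is.matrix(x)) list(x) else x
}

#' Weighted average cross-entropy over row classifications
#'
#' Every row of a prediction matrix together with the matching one-hot label
#' row is one sub-sample; a batch of b length-L predictions has bL
#' sub-samples. Because most bases are unpaired (their label 1 sits on the
#' diagonal), the unpaired sub-samples D are down-weighted by
#' `(bL - |D|) / |D|`:
#' `loss = (1/bL) * (sum_{i not in D} l_i + (bL - |D|)/|D| * sum_{i in D} l_i)`.
#' Padded rows (pad mask 0) are excluded from both sums and from the bL
#' count, so a sample's contribution does not depend on how it was batched.
#'
#' Degenerate cases: with no unpaired sub-sample the second sum is empty and
#' the loss is the plain average of the paired terms; with *only* unpaired
#' sub-samples the formula would vanish identically, so the plain unweighted
#' mean is used instead. Both fallbacks emit a message.
#'
#' @param Pr a row-stochastic probability matrix ([row_softmax()] output) or
#'   a list of them (a batch).
#' @param labels the matching diagonal-filled label matrix/matrices
#'   ([modify_label()] output); every row must be one-hot.
#' @param pad_mask optional logical vector or list of vectors, TRUE for real
#'   rows; defaults to all TRUE.
#' @return The scalar loss.
#' @export
weighted_cross_entropy <- function(Pr, labels, pad_mask = NULL) {
  Pr <- as_matrix_batch(Pr)
  labels <- as_matrix_batch(labels)
  stopifnot(length(Pr) == length(labels))
  if (is.null(pad_mask)) {
    pad_mask <- lapply(Pr, function(m) rep(TRUE, nrow(m)))
  } else if (!is.list(pad_mask)) {
    pad_mask <- list(pad_mask)
  }
  li <- numeric(0)      # per-sub-sample cross-entropies
  unpaired <- logical(0)
  for (k in seq_along(Pr)) {
    P <- Pr[[k]]
    S <- labels[[k]]
    stopifnot(is.matrix(P), all(dim(P) == dim(S)))
    keep <- which(pad_mask[[k]])
    if (length(keep) == 0L) next
    cls <- max.col(S[keep, , drop = FALSE], ties.method = "first")
    if (!all(abs(rowSums(S[keep, , drop = FALSE]) - 1) < 1e-9))
      stop("label rows must be one-hot", call. = FALSE)
    p <- P[cbind(keep, cls)]
    li <- c(li, -log(pmax(p, .Machine$double.xmin)))
    unpaired <- c(unpaired, cls == keep)
  }
  weighted_ce_from_terms(li, unpaired)
}

# Core of the weighted objective, shared with the training path.
weighted_ce_from_terms <- function(li, unpaired) {
  n <- length(li)
  if (n == 0L) stop("no sub-samples to average over", call. = FALSE)
  nD <- sum(unpaired)
  if (nD == 0L) {
    message("weighted cross-entropy: no unpaired sub-samples; ",
            "using plain average of paired terms")
    return(mean(li))
  }
  if (nD == n) {
    message("weighted cross-entropy: all sub-samples unpaired; ",
            "falling back to the unweighted mean")
    return(mean(li))
  }
  (sum(li[!unpaired]) + (n - nD) / nD * sum(li[unpaired])) / n
}

# per-sub-sample weights implied by the objective (0 rows handled upstream)
weighted_ce_weights <- function(unpaired) {
  n <- length(unpaired)
  nD <- sum(unpaired)
  w <- rep(1, n)
  if (nD == 0L || nD == n) return(w / n)
  w[unpaired] <- (n - nD) / nD
  w / n
}

#' Column-labelled counterpart of the weighted cross-entropy
#'
#' Treats each *column* of the prediction as a classification against the
#' matching label column (softmax down columns). Because both the
#' symmetrized score matrix and the diagonal-filled label are symmetric,
#' training on columns of the transposed scores is equivalent to training on
#' rows — this function exists to state that equivalence as a testable fact.
#'
#' @inheritParams weighted_cross_entropy
#' @param Pc a column-stochastic matrix or list of them.
#' @return The scalar loss.
#' @export
weighted_cross_entropy_cols <- function(Pc, labels, pad_mask = NULL) {
  Pc <- as_matrix_batch(Pc)
  labels <- as_matrix_batch(labels)
  weighted_cross_entropy(lapply(Pc, t), lapply(labels, t), pad_mask)
}

#' Column-wise softmax
#'
#' @param Mhat a numeric matrix with finite entries.
#' @return A matrix whose columns sum to 1.
#' @export
col_softmax <- function(Mhat) t(row_softmax(t(Mhat)))

# Loss and gradient with respect to the (symmetrized) score matrix, for the
# training loop: log-softmax based, single sample, no padding rows.
# Returns list(loss, grad) where grad has the same shape as Mhat.
wce_scores_grad <- function(Mhat, Shat) {
  L <- nrow(Mhat)
  logP <- row_log_softmax(Mhat)
  cls <- max.col(Shat, ties.method = "first")
  li <- -logP[cbind(seq_len(L), cls)]
  unpaired <- cls == seq_len(L)
  w <- weighted_ce_weights(unpaired)
  loss <- sum(w * li)
  P <- exp(logP)
  G <- P * w                      # length-L w recycles column-major: row i scaled by w[i]
  G[cbind(seq_len(L), cls)] <- G[cbind(seq_len(L), cls)] - w
  list(loss = loss, grad = G)
}
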