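#' Audit a binary matrix against the structure-validity constraints
#'
#' Checks the validity rules a base-pair contact matrix must satisfy:
#' binary entries, symmetry, at most one 1 per row and per column, and no
#' entries in the sharp-loop band `|i - j| < 4` (which includes the
#' diagonal). Pairing chemistry is deliberately *not* a validity rule — the
#' model is free to predict non-canonical pairs — but when a sequence is
#' supplied, non-canonical pairs are reported informationally via the
#' `"info"` attribute.
#'
#' @param S a square numeric matrix.
#' @param seq optional [rna_sequence()] for the informational pairing report.
#' @return A character vector of violations (empty when the matrix is a valid
#'   structure matrix), with attribute `info` carrying informational notes.
#' @export
audit_validity <- function(S, seq = NULL) {
  v <- character(0)
  info <- character(0)
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    return(structure("matrix is not square", info = info))
  }
  L <- nrow(S)
  if (!all(S %in% c(0, 1))) {
    bad <- which(!(S %in% c(0, 1)))[1L]
    v <- c(v, sprintf("not binary: entry (%d, %d) = %g",
                      (bad - 1L) %% L + 1L, (bad - 1L) %/% L + 1L, S[bad]))
  } else {
    asym <- which(S != t(S), arr.ind = TRUE)
    if (nrow(asym) > 0L) {
      a <- asym[1L, ]
      v <- c(v, sprintf("not symmetric: entry (%d, %d) != (%d, %d)",
                        a[1L], a[2L], a[2L], a[1L]))
    }
    rs <- rowSums(S)
    if (any(rs > 1)) {
      v <- c(v, sprintf("more than one partner in row %s",
                        paste(which(rs > 1), collapse = ", ")))
    }
    cs <- colSums(S)
    if (any(cs > 1)) {
      v <- c(v, sprintf("more than one partner in column %s",
                        paste(which(cs > 1), collapse = ", ")))
    }
    band <- abs(row(S) - col(S)) < 4
    if (any(S[band] != 0)) {
      b <- which(S != 0 & band, arr.ind = TRUE)
      v <- c(v, sprintf("sharp loop: entry (%d, %d) with |i - j| < 4",
                        b[1L, 1L], b[1L, 2L]))
    }
    if (!is.null(seq) && length(v) == 0L) {
      ch <- seq_chars(seq)
      up <- which(S == 1 & upper.tri(S), arr.ind = TRUE)
      if (nrow(up) > 0L) {
        kinds <- paste0(ch[up[, 1L]], ch[up[, 2L]])
        nc <- !(kinds %in% CANONICAL_PAIRS)
        if (any(nc))
          info <- sprintf("non-canonical pair %s at (%d, %d)",
                          kinds[nc], up[nc, 1L], up[nc, 2L])
      }
    }
  }
  structure(v, info = info)
}

is_valid_structure <- function(S) length(audit_validity(S)) == 0L

#' Diagonal-fill label transformation
#'
#' Turns a structure matrix into a one-hot-per-row classification label by
#' placing a 1 on the diagonal of every zero row: an unpaired base is
#' labelled as "pairing with itself". The result is a symmetric permutation
#' matrix (an involution), so each of the L rows is the target of an L-class
#' classification. The transform is lossless off the diagonal.
#'
#' @param S a valid L x L structure matrix.
#' @return An L x L symmetric permutation matrix.
#' @export
modify_label <- function(S) {
  v <- audit_validity(S)
  if (length(v) > 0L)
    stop("invalid structure matrix:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  Shat <- S
  diag(Shat) <- 1 - rowSums(S)
  Shat
}

#' Symmetrize a score matrix
#'
#' Averages a raw model score matrix with its transpose so that position
#' (i, j) and (j, i) carry the same score before row-wise decoding.
#'
#' @param M a square numeric matrix.
#' @return `(M + t(M)) / 2`.
#' @export
symmetrize <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("score matrix must be square", call. = FALSE)
  (M + t(M)) / 2
}

#' Binarize each row at its maximum
#'
#' Sets the largest entry of each row to 1 and the rest to 0. Ties break to
#' the lowest column index so results are deterministic.
#'
#' @param Mhat a square numeric matrix.
#' @return A binary matrix with exactly one 1 per row.
#' @export
row_argmax_binarize <- function(Mhat) {
  if (!is.matrix(Mhat) || nrow(Mhat) != ncol(Mhat))
    stop("score matrix must be square", call. = FALSE)
  L <- nrow(Mhat)
  P <- matrix(0, L, L)
  P[cbind(seq_len(L), max.col(Mhat, ties.method = "first"))] <- 1
  P
}

#' Sharp-loop mask
#'
#' The binary mask with zeros where `|i - j| < 4` (pairs that would close a
#' loop of fewer than three bases, including the diagonal itself) and ones
#' elsewhere.
#'
#' @param L sequence length.
#' @return An L x L binary mask matrix.
#' @export
sharp_loop_mask <- function(L) {
  stopifnot(L >= 1L)
  Z <- matrix(1, L, L)
  Z[abs(row(Z) - col(Z)) < 4] <- 0
  Z
}

#' Decode a score matrix into a guaranteed-valid structure
#'
#' The decoder needs no iterative post-processing: symmetrize the scores,
#' binarize each row at its maximum, take the element-wise product with the
#' transpose (so a pair survives only when bases i and j select each other),
#' and apply the sharp-loop mask. The result is always binary, symmetric,
#' has at most one partner per base and no sharp loops — for any real input,
#' trained model or not. Bases whose row maximum falls on the diagonal
#' ("pair with itself") decode to unpaired because the mask zeroes the
#' diagonal.
#'
#' @param Mhat a square numeric score matrix; symmetrized internally if it
#'   is not already symmetric.
#' @return A valid binary prediction matrix.
#' @export
decode_structure <- function(Mhat) {
  Mhat <- symmetrize(Mhat)
  Pr <- row_argmax_binarize(Mhat)
  Pr * t(Pr) * sharp_loop_mask(nrow(Mhat))
}
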