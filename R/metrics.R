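#' Confusion counts over candidate pair positions
#'
#' Counts true/false positives and negatives between a predicted and a
#' reference structure matrix. Each unordered pair (i, j) with `j - i >= 4`
#' is one candidate position, so a base pair is counted once and positions
#' that are structurally forced to zero in *both* matrices (the diagonal and
#' the sharp-loop band) are excluded from the universe. For L >= 4 the
#' universe size is (L - 4)(L - 3)/2.
#'
#' @param pred predicted L x L binary structure matrix.
#' @param ref reference L x L binary structure matrix.
#' @return A named list with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, ref) {
  if (!is.matrix(pred) || !is.matrix(ref) || !all(dim(pred) == dim(ref)))
    stop("prediction and reference must be matrices of equal size",
         call. = FALSE)
  idx <- which(col(pred) - row(pred) >= 4)
  p <- pred[idx] == 1
  r <- ref[idx] == 1
  list(TP = sum(p & r), FP = sum(p & !r), TN = sum(!p & !r), FN = sum(!p & r))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. When prediction and
#' reference are both empty (TP = FP = FN = 0) the structures agree exactly
#' and all three scores are 1; otherwise any 0/0 term is taken as 0.
#'
#' @param counts output of [confusion_counts()].
#' @return Named numeric vector with elements `P`, `R`, `F1`.
#' @export
precision_recall_f1 <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if (TP == 0 && FP == 0 && FN == 0)
    return(c(P = 1, R = 1, F1 = 1))
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

#' Interaction network fidelity (INF)
#'
#' `INF = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, computed
#' identically to the Matthews correlation coefficient on the pair-level
#' confusion counts. A zero factor in the denominator yields 0, the standard
#' MCC convention.
#'
#' @param counts output of [confusion_counts()].
#' @return A scalar in \[-1, 1\].
#' @export
inf_score <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Score a set of predictions against references
#'
#' @param preds list of predicted structure matrices.
#' @param refs list of reference structure matrices (same order).
#' @param lengths optional integer vector of sequence lengths (defaults to
#'   the matrix sizes).
#' @param families optional character vector of family tags.
#' @return A data frame with one row per sample: `L`, `family`, `P`, `R`,
#'   `F1`, `INF`.
#' @export
score_predictions <- function(preds, refs, lengths = NULL, families = NULL) {
  stopifnot(length(preds) == length(refs))
  n <- length(preds)
  if (is.null(lengths)) lengths <- vapply(refs, nrow, integer(1L))
  if (is.null(families)) families <- rep(NA_character_, n)
  rows <- lapply(seq_len(n), function(k) {
    cc <- confusion_counts(preds[[k]], refs[[k]])
    prf <- precision_recall_f1(cc)
    data.frame(L = lengths[k], family = families[k], P = prf[["P"]],
               R = prf[["R"]], F1 = prf[["F1"]], INF = inf_score(cc))
  })
  do.call(rbind, rows)
}

#' Stratified score report
#'
#' Macro-averages per-sample scores (mean and standard deviation across
#' samples) overall, per sequence-length bin, and per family tag when tags
#' are present. Default bins split at 150 — the conventional short/long
#' boundary — inside the 50-500 working range; `fine = TRUE` adds width-100
#' bins. Empty groups are omitted rather than reported as zero.
#'
#' @param scores data frame from [score_predictions()].
#' @param breaks numeric break points for the length bins.
#' @param fine also report width-100 length bins.
#' @return A data frame with columns `group`, `n`, and mean/sd columns for
#'   each score.
#' @export
stratified_report <- function(scores, breaks = c(50, 150, 500), fine = FALSE) {
  stopifnot(nrow(scores) > 0L)
  groups <- list(Overall = seq_len(nrow(scores)))
  add_bins <- function(groups, brk) {
    for (b in seq_len(length(brk) - 1L)) {
      lab <- sprintf("%g<L<=%g", brk[b], brk[b + 1L])
      idx <- which(scores$L > brk[b] & scores$L <= brk[b + 1L])
      if (length(idx) > 0L) groups[[lab]] <- idx
    }
    groups
  }
  groups <- add_bins(groups, breaks)
  if (fine) {
    lo <- floor(min(scores$L) / 100) * 100
    hi <- ceiling(max(scores$L) / 100) * 100
    groups <- add_bins(groups, seq(lo, hi, by = 100))
  }
  if (any(!is.na(scores$family))) {
    for (fam in sort(unique(scores$family[!is.na(scores$family)]))) {
      groups[[paste0("family:", fam)]] <- which(scores$family %in% fam)
    }
  }
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    s <- scores[idx, , drop = FALSE]
    data.frame(group = g, n = length(idx),
               P_mean = mean(s$P), P_sd = sd(s$P),
               R_mean = mean(s$R), R_sd = sd(s$R),
               F1_mean = mean(s$F1), F1_sd = sd(s$F1),
               INF_mean = mean(s$INF), INF_sd = sd(s$INF))
  })
  do.call(rbind, rows)
}
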