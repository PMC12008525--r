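#' Compute raw score matrices for a batch of sequences
#'
#' Runs the scoring network forward. Each sequence is right-padded to a
#' multiple of `2^unet_depth`; the padded region is masked out of attention
#' and zeroed before the pairwise grid, and only the real L x L block is
#' returned. Raw scores are *not* symmetrized here — symmetrization belongs
#' to the caller's decoding/loss step.
#'
#' @param net a [build_model()] network.
#' @param seqs a list of [rna_sequence()] objects (or character strings).
#' @return A list of L x L raw score matrices.
#' @export
forward_scores <- function(net, seqs) {
  stopifnot(inherits(net, "fold_model"))
  if (inherits(seqs, "rna_sequence") || is.character(seqs)) seqs <- list(seqs)
  lapply(seqs, function(s) forward_single(net, as_rna_sequence(s))$M)
}

#' Train the scoring network
#'
#' Plain stochastic training: per-epoch shuffling, one sample per step, Adam
#' updates on the weighted row-classification cross-entropy of the
#' symmetrized scores against the diagonal-filled labels. Each epoch is
#' seeded as `seed + 101 * epoch`, so a run resumed from a checkpoint at an
#' epoch boundary reproduces an uninterrupted run step for step.
#'
#' @param net a [build_model()] network (or a loaded checkpoint).
#' @param samples list of [rna_sample()] training samples.
#' @param epochs number of passes over the data.
#' @param lr Adam learning rate.
#' @param seed base seed for shuffling (and dropout, if enabled).
#' @param checkpoint optional path: the network is saved there after every
#'   epoch via [save_checkpoint()].
#' @param verbose print the mean loss after each epoch.
#' @return The trained network; `$trace` holds the per-epoch mean loss.
#' @export
train_model <- function(net, samples, epochs = 10L, lr = 2e-3, seed = 1L,
                        checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "fold_model"))
  if (length(samples) == 0L) stop("empty training set", call. = FALSE)
  start_epoch <- length(net$trace)
  for (ep in (start_epoch + 1L):(start_epoch + epochs)) {
    set.seed(seed + 101L * ep)
    ord <- sample(length(samples))
    total <- 0
    for (k in ord) {
      s <- samples[[k]]
      fwd <- forward_single(net, s$seq, train = TRUE)
      Mhat <- symmetrize(fwd$M)
      lg <- wce_scores_grad(Mhat, modify_label(s$structure))
      dM <- (lg$grad + t(lg$grad)) / 2     # back through symmetrization
      grads <- backward_single(net, fwd, dM)
      upd <- adam_step(net$params, grads, net$opt, lr)
      net$params <- upd$params
      net$opt <- upd$state
      total <- total + lg$loss
    }
    net$trace <- c(net$trace, total / length(samples))
    if (verbose)
      message(sprintf("epoch %d: mean loss %.4f", ep, net$trace[ep]))
    if (!is.null(checkpoint)) save_checkpoint(net, checkpoint)
  }
  net
}

# mean loss over a sample set without updating parameters
evaluate_loss <- function(net, samples) {
  mean(vapply(samples, function(s) {
    Mhat <- symmetrize(forward_single(net, s$seq)$M)
    wce_scores_grad(Mhat, modify_label(s$structure))$loss
  }, numeric(1L)))
}

#' Predict valid secondary structures
#'
#' Forward pass, symmetrization, then the guaranteed-valid decoder. Every
#' returned matrix passes [audit_validity()] with zero violations whether or
#' not the network has been trained.
#'
#' @param net a [build_model()] network.
#' @param seqs list of [rna_sequence()] objects (or character strings).
#' @return A list of binary prediction matrices (empty for empty input).
#' @export
predict_structures <- function(net, seqs) {
  if (length(seqs) == 0L) return(list())
  lapply(forward_scores(net, seqs), decode_structure)
}

#' @export
predict.fold_model <- function(object, seqs, ...) {
  predict_structures(object, seqs)
}

#' Save / load a network checkpoint
#'
#' The checkpoint carries the parameters, config (including the init seed),
#' optimiser state and loss trace, so training can resume deterministically.
#'
#' @param net a `fold_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `fold_model` (load).
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "fold_model"))
  saveRDS(unclass(net), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "fold_model")
}

#' Mean F1 of a network over labelled samples
#'
#' Convenience wrapper: predict every sample's structure and macro-average
#' the per-sample F1 against the reference structures.
#'
#' @param net a `fold_model`.
#' @param samples list of [rna_sample()] objects.
#' @return Mean per-sample F1.
#' @export
mean_f1 <- function(net, samples) {
  preds <- predict_structures(net, lapply(samples, function(s) s$seq))
  refs <- lapply(samples, function(s) s$structure)
  mean(score_predictions(preds, refs)$F1)
}
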