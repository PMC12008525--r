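# Data augmentation for RNA samples. Only bases that form no base pair are
# ever touched, so the assigned structure remains a plausible label for the
# augmented sequence; pair counts are conserved by all three operators.

#' Indices of unpaired bases
#'
#' @param S a valid L x L structure matrix.
#' @return Sorted integer vector of 1-based indices whose rows are all zero.
#' @export
unpaired_indices <- function(S) {
  which(rowSums(S) == 0)
}

as_sample <- function(x) {
  stopifnot(inherits(x, "rna_sample"))
  x
}

#' Add substitution noise to unpaired bases
#'
#' Selects `round(p1 * |B|)` bases (round half up) from the unpaired set B
#' and changes each to one of the three *other* bases, chosen uniformly.
#' Paired bases and the structure matrix are untouched: the original
#' structure is reused as the label of the augmented sequence.
#'
#' @param sample an [rna_sample()].
#' @param p1 noise fraction in \[0, 1\].
#' @param id identifier for the augmented sample (default keeps the old one).
#' @return A new [rna_sample()].
#' @export
add_noise <- function(sample, p1 = 0.10, id = NULL) {
  sample <- as_sample(sample)
  B <- unpaired_indices(sample$structure)
  k <- round_half_up(p1 * length(B))
  ch <- seq_chars(sample$seq)
  if (k > 0L) {
    sel <- if (length(B) == 1L) B else sample(B, k)
    for (i in sel) ch[i] <- sample(setdiff(RNA_BASES, ch[i]), 1L)
  }
  rna_sample(rna_sequence(if (is.null(id)) sample$seq$id else id,
                          paste(ch, collapse = ""), normalize = FALSE),
             sample$structure, family = sample$family)
}

# pair list after deleting the (sorted) index set `del`: shift each index by
# the number of deleted positions before it
shift_pairs_after_deletion <- function(pairs, del) {
  if (nrow(pairs) == 0L) return(pairs)
  shift <- function(v) v - vapply(v, function(i) sum(del < i), integer(1L))
  cbind(shift(pairs[, 1L]), shift(pairs[, 2L]))
}

#' Remove unpaired bases
#'
#' Deletes `round(p2 * |B|)` bases from the unpaired set and drops the
#' corresponding rows and columns of the structure, then applies
#' [add_noise()] with `p1` to the shortened sample. A candidate deletion
#' that would squeeze a surviving pair below separation 4 (shrinking a loop
#' under three bases) is resampled, so the output always passes the audit.
#'
#' @param sample an [rna_sample()].
#' @param p2 removal fraction.
#' @param p1 noise fraction applied afterwards.
#' @param id identifier for the augmented sample.
#' @return A new [rna_sample()] of length `L - round(p2 * |B|)`.
#' @export
remove_bases <- function(sample, p2 = 0.10, p1 = 0.10, id = NULL) {
  sample <- as_sample(sample)
  S <- sample$structure
  B <- unpaired_indices(S)
  k <- round_half_up(p2 * length(B))
  pairs <- matrix_to_pairs(S)$pairs
  chosen <- integer(0)
  candidates <- B
  while (length(chosen) < k && length(candidates) > 0L) {
    cand <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
    candidates <- setdiff(candidates, cand)
    del <- sort(c(chosen, cand))
    newp <- shift_pairs_after_deletion(pairs, del)
    if (nrow(pairs) == 0L || all(newp[, 2L] - newp[, 1L] >= 4L))
      chosen <- c(chosen, cand)
  }
  if (length(chosen) < k)
    warning(sprintf("could only remove %d of %d requested bases without creating sharp loops",
                    length(chosen), k))
  del <- sort(chosen)
  ch <- seq_chars(sample$seq)
  keep <- setdiff(seq_along(ch), del)
  newL <- length(keep)
  pm <- pair_map(newL, shift_pairs_after_deletion(pairs, del))
  out <- rna_sample(rna_sequence(if (is.null(id)) sample$seq$id else id,
                                 paste(ch[keep], collapse = ""),
                                 normalize = FALSE),
                    pm, family = sample$family)
  add_noise(out, p1)
}

#' Insert random bases at unpaired positions
#'
#' Chooses `round(p3 * L)` insertion points without replacement among the
#' L + 1 inter-base gaps, inserts one uniform random base at each, adds the
#' matching zero rows and columns to the structure, then applies
#' [add_noise()] with `p1`. Inserted bases are unpaired by construction and
#' existing pair indices shift accordingly.
#'
#' @param sample an [rna_sample()].
#' @param p3 insertion fraction.
#' @param p1 noise fraction applied afterwards.
#' @param id identifier for the augmented sample.
#' @return A new [rna_sample()] of length `L + round(p3 * L)`.
#' @export
insert_bases <- function(sample, p3 = 0.10, p1 = 0.10, id = NULL) {
  sample <- as_sample(sample)
  L <- length(sample$seq)
  k <- round_half_up(p3 * L)
  gaps <- if (k > 0L) sort(sample(0:L, k)) else integer(0)  # gap g = after base g
  ch <- seq_chars(sample$seq)
  pairs <- matrix_to_pairs(sample$structure)$pairs
  # offset for an original index i: number of insertion gaps strictly before it
  if (k > 0L) {
    newL <- L + k
    inserted_at <- gaps + seq_len(k)  # positions of inserted bases in the new sequence
    newch <- character(newL)
    newch[inserted_at] <- random_bases(k)
    newch[-inserted_at] <- ch
    if (nrow(pairs) > 0L) {
      off <- function(v) v + vapply(v, function(i) sum(gaps < i), integer(1L))
      pairs <- cbind(off(pairs[, 1L]), off(pairs[, 2L]))
    }
    ch <- newch
    L <- newL
  }
  pm <- pair_map(L, pairs)
  out <- rna_sample(rna_sequence(if (is.null(id)) sample$seq$id else id,
                                 paste(ch, collapse = ""), normalize = FALSE),
                    pm, family = sample$family)
  add_noise(out, p1)
}

#' Augment a dataset
#'
#' Applies the three operators (noise, remove, insert) `reps` times each to
#' every sample passing the length gate, appending the augmented samples to
#' the originals. With the default gate (150 < L <= 500) and `reps = 2`,
#' each long sample yields six augmented samples; shorter samples pass
#' through unaugmented. Augmented identifiers record operator and
#' repetition.
#'
#' @param samples list of [rna_sample()] objects.
#' @param p1,p2,p3 the three augmentation fractions.
#' @param reps repetitions of each operator per sample.
#' @param min_len,max_len the length gate: augment only samples with
#'   `min_len < L <= max_len`.
#' @param seed optional seed; the whole augmented dataset is reproducible
#'   from it.
#' @return A list: the original samples followed by the augmented ones.
#' @export
augment_dataset <- function(samples, p1 = 0.10, p2 = 0.10, p3 = 0.10,
                            reps = 2L, min_len = 150L, max_len = 500L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (s in samples) {
    L <- length(s$seq)
    if (L <= min_len || L > max_len) next
    for (r in seq_len(reps)) {
      out <- c(out, list(
        add_noise(s, p1, id = sprintf("%s|noise|rep%d", s$seq$id, r)),
        remove_bases(s, p2, p1, id = sprintf("%s|remove|rep%d", s$seq$id, r)),
        insert_bases(s, p3, p1, id = sprintf("%s|insert|rep%d", s$seq$id, r))))
    }
  }
  c(samples, out)
}
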