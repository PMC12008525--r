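# Synthetic RNA samples with known valid structures. Stems draw from the six
# canonical + wobble complements so that pairing is learnable from sequence;
# loop and linker bases are uniform over A/U/C/G. Every generator output is
# valid by construction and double-checked by the auditor.

sample_complement <- function(n) {
  # returns a 2 x n matrix of (left, right) stem bases
  kinds <- sample(CANONICAL_PAIRS, n, replace = TRUE)
  vapply(strsplit(kinds, ""), identity, character(2L))
}

random_bases <- function(n) {
  if (n == 0L) return(character(0))
  sample(RNA_BASES, n, replace = TRUE)
}

#' Generate a random hairpin sample
#'
#' A stem of `stem` complementary pairs closing a loop of `loop` unpaired
#' bases: pairs are (i, L + 1 - i) for i = 1..stem, with L = 2*stem + loop.
#' The loop must have at least 3 bases so the innermost pair respects the
#' sharp-loop rule (separation >= 4).
#'
#' @param stem number of stem pairs (>= 1).
#' @param loop number of loop bases (>= 3).
#' @param id identifier for the sample.
#' @return An [rna_sample()] with family tag `"hairpin"`.
#' @export
make_hairpin <- function(stem, loop, id = "hairpin") {
  if (loop < 3L) stop("loop must have >= 3 bases (sharp-loop rule)", call. = FALSE)
  if (stem < 1L) stop("stem must have >= 1 pair", call. = FALSE)
  L <- 2L * stem + loop
  ch <- character(L)
  comp <- sample_complement(stem)
  for (i in seq_len(stem)) {
    ch[i] <- comp[1L, i]
    ch[L + 1L - i] <- comp[2L, i]
  }
  ch[(stem + 1L):(stem + loop)] <- random_bases(loop)
  pm <- pair_map(L, cbind(seq_len(stem), L + 1L - seq_len(stem)))
  rna_sample(rna_sequence(id, paste(ch, collapse = "")), pm, family = "hairpin")
}

#' Generate a two-stem (multi-loop-free) sample
#'
#' Two independent hairpins joined by an unpaired linker.
#'
#' @param stems integer vector of two stem lengths.
#' @param loops integer vector of two loop lengths (each >= 3).
#' @param linker number of unpaired bases between the hairpins.
#' @param id identifier.
#' @return An [rna_sample()] with family tag `"two_stem"`.
#' @export
make_two_stem <- function(stems = c(4L, 4L), loops = c(4L, 4L), linker = 4L,
                          id = "two_stem") {
  h1 <- make_hairpin(stems[1L], loops[1L])
  h2 <- make_hairpin(stems[2L], loops[2L])
  L1 <- length(h1$seq)
  bases <- paste0(h1$seq$bases, paste(random_bases(linker), collapse = ""),
                  h2$seq$bases)
  pm1 <- matrix_to_pairs(h1$structure)$pairs
  pm2 <- matrix_to_pairs(h2$structure)$pairs + L1 + linker
  pm <- pair_map(nchar(bases), rbind(pm1, pm2))
  rna_sample(rna_sequence(id, bases), pm, family = "two_stem")
}

#' Generate an H-type pseudoknot sample
#'
#' Two stems whose pairs cross: segment layout
#' `stem1 | loop1 | stem2 | loop2 | stem1' | loop3 | stem2'`, with stem1
#' pairing across stem2's left arm and vice versa. The geometry must leave
#' every pair separation >= 4.
#'
#' @param s1,s2 stem lengths of the two crossing stems.
#' @param loops integer vector of the three loop/linker lengths.
#' @param id identifier.
#' @return An [rna_sample()] with family tag `"pseudoknot"`; its pairs
#'   contain at least one crossing pair of pairs.
#' @export
make_pseudoknot <- function(s1 = 3L, s2 = 3L, loops = c(3L, 3L, 3L),
                            id = "pseudoknot") {
  l1 <- loops[1L]; l2 <- loops[2L]; l3 <- loops[3L]
  a <- 0L
  b <- s1 + l1
  cc <- b + s2 + l2
  d <- cc + s1 + l3
  L <- d + s2
  p1 <- cbind(a + seq_len(s1), cc + s1 + 1L - seq_len(s1))
  p2 <- cbind(b + seq_len(s2), d + s2 + 1L - seq_len(s2))
  if (any(c(p1[, 2L] - p1[, 1L], p2[, 2L] - p2[, 1L]) < 4L))
    stop("pseudoknot geometry infeasible: a pair separation falls below 4",
         call. = FALSE)
  ch <- random_bases(L)
  for (p in list(p1, p2)) {
    comp <- sample_complement(nrow(p))
    ch[p[, 1L]] <- comp[1L, ]
    ch[p[, 2L]] <- comp[2L, ]
  }
  pm <- pair_map(L, rbind(p1, p2))
  rna_sample(rna_sequence(id, paste(ch, collapse = "")), pm,
             family = "pseudoknot")
}

#' Generate a reproducible dataset of synthetic samples
#'
#' Draws motif kinds from `motifs` (a named probability vector over
#' `hairpin`, `two_stem`, `pseudoknot`), with stem and loop sizes uniform
#' over the given ranges.
#'
#' @param n number of samples.
#' @param motifs named weights over motif kinds.
#' @param stem_range,loop_range inclusive ranges for stem pairs / loop bases.
#' @param seed optional seed for reproducibility.
#' @return A list of [rna_sample()] objects.
#' @export
make_fixture_dataset <- function(n,
                                 motifs = c(hairpin = 1),
                                 stem_range = c(3L, 12L),
                                 loop_range = c(3L, 10L),
                                 seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  kinds <- sample(names(motifs), n, replace = TRUE, prob = motifs)
  lapply(seq_len(n), function(k) {
    s <- sample(stem_range[1L]:stem_range[2L], 1L)
    l <- sample(loop_range[1L]:loop_range[2L], 1L)
    id <- sprintf("%s_%04d", kinds[k], k)
    switch(kinds[k],
           hairpin = make_hairpin(s, l, id = id),
           two_stem = make_two_stem(c(s, s), c(l, l), linker = max(4L, l),
                                    id = id),
           pseudoknot = make_pseudoknot(max(2L, s %/% 2L), max(2L, s %/% 2L),
                                        loops = c(l, l, l), id = id),
           stop("unknown motif kind: ", kinds[k], call. = FALSE))
  })
}
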