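#' RNA sequence object
#'
#' A lightweight container for a single RNA sequence: an identifier and a
#' base string over the alphabet A, U, C, G. `normalize = TRUE` applies the
#' common clean-up for FASTA from the wild (lower case to upper case, DNA
#' T to U) before validation.
#'
#' @param id character scalar, the sequence identifier.
#' @param bases character scalar over A/U/C/G (after normalization).
#' @param normalize logical; apply case folding and T->U first.
#' @return An object of class `rna_sequence` with fields `id` and `bases`.
#' @examples
#' rna_sequence("x", "ggtaacc")  # normalized to GGUAACC
#' @export
rna_sequence <- function(id, bases, normalize = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(bases), length(bases) == 1L)
  if (normalize) {
    bases <- toupper(bases)
    bases <- gsub("T", "U", bases, fixed = TRUE)
  }
  bad <- setdiff(unique(strsplit(bases, "")[[1]]), RNA_BASES)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': invalid characters after normalization: %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(id = id, bases = bases), class = "rna_sequence")
}

#' @export
length.rna_sequence <- function(x) nchar(x$bases)

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (L = %d)\n", x$id, length(x)), x$bases, "\n")
  invisible(x)
}

# coerce character / rna_sequence to rna_sequence
as_rna_sequence <- function(x, id = "seq") {
  if (inherits(x, "rna_sequence")) return(x)
  rna_sequence(id, x)
}

seq_chars <- function(seq) strsplit(seq$bases, "")[[1]]

#' Base-pair map
#'
#' The set of base pairs of a structure of length `L`, stored as a two-column
#' integer matrix of 1-based index pairs with `i < j`. Validity is enforced on
#' construction: indices in range, each base in at most one pair, and no
#' sharp loops (`j - i >= 4`, i.e. at least three unpaired bases between the
#' arms of the innermost pair).
#'
#' @param length sequence length L.
#' @param pairs two-column matrix (or empty) of index pairs, 1-based.
#' @return An object of class `pair_map` with fields `length` and `pairs`
#'   (sorted two-column integer matrix).
#' @examples
#' pair_map(10, rbind(c(1, 10)))
#' @export
pair_map <- function(length, pairs = NULL) {
  L <- as.integer(length)
  stopifnot(L >= 1L)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    pairs <- t(apply(pairs, 1L, sort))
    if (NROW(pairs) == 1L) pairs <- matrix(pairs, ncol = 2L)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    if (any(pairs < 1L) || any(pairs > L))
      stop("pair index out of range [1, L]", call. = FALSE)
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("a base appears in more than one pair", call. = FALSE)
    sep <- pairs[, 2L] - pairs[, 1L]
    if (any(sep < 4L))
      stop("sharp loop: pair with |i - j| < 4", call. = FALSE)
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(length = L, pairs = pairs), class = "pair_map")
}

#' @export
print.pair_map <- function(x, ...) {
  cat(sprintf("<pair_map> L = %d, %d pairs\n", x$length, nrow(x$pairs)))
  invisible(x)
}

n_pairs <- function(pm) nrow(pm$pairs)

pair_map_equal <- function(a, b) {
  a$length == b$length && nrow(a$pairs) == nrow(b$pairs) &&
    all(a$pairs == b$pairs)
}

# partner vector: partner[i] = j if {i, j} paired, 0 if unpaired
partner_vector <- function(pm) {
  p <- integer(pm$length)
  if (nrow(pm$pairs) > 0L) {
    p[pm$pairs[, 1L]] <- pm$pairs[, 2L]
    p[pm$pairs[, 2L]] <- pm$pairs[, 1L]
  }
  p
}

#' Bundle a sequence and its structure into a labelled sample
#'
#' @param seq an [rna_sequence()] (or character string).
#' @param structure an L x L binary structure matrix, or a [pair_map()].
#' @param family optional family/motif tag used by [stratified_report()].
#' @return An object of class `rna_sample` with fields `seq`, `structure`
#'   (always stored as a matrix) and `family`.
#' @export
rna_sample <- function(seq, structure, family = NA_character_) {
  seq <- as_rna_sequence(seq)
  if (inherits(structure, "pair_map")) structure <- pairs_to_matrix(structure)
  stopifnot(is.matrix(structure), nrow(structure) == length(seq))
  structure(list(seq = seq, structure = structure, family = family),
            class = "rna_sample")
}

#' @export
print.rna_sample <- function(x, ...) {
  cat(sprintf("<rna_sample> %s (L = %d, %d pairs%s)\n", x$seq$id,
              length(x$seq), sum(x$structure) / 2L,
              if (is.na(x$family)) "" else paste0(", family = ", x$family)))
  invisible(x)
}
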