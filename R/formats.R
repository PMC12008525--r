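#' Read RNA sequences from a FASTA file
#'
#' Records are normalized before validation: lower case is folded to upper
#' case and DNA-style T becomes U. Any other character is a format error
#' naming the offending record.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A list of [rna_sequence()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("FASTA record with empty header in ", path, call. = FALSE)
  # keep only the first whitespace-delimited token of each header
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  lapply(seq_along(set), function(k) rna_sequence(ids[k], as.character(set[[k]])))
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs a list of [rna_sequence()] objects (or one such object).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, function(s) s$bases, character(1L)))
  names(set) <- vapply(seqs, function(s) s$id, character(1L))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a secondary structure in CT (connectivity table) format
#'
#' Expects the dominant 6-column CT dialect: a header line whose first token
#' is the sequence length L (any further tokens are taken as the identifier),
#' followed by L rows of `index base prev next partner index`, 1-based, with
#' partner 0 meaning unpaired. Partner columns must be mutually consistent.
#'
#' @param path path to a CT file.
#' @return A list with elements `seq` ([rna_sequence()]) and `pairs`
#'   ([pair_map()]).
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop("CT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty CT file: ", path, call. = FALSE)
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  L <- suppressWarnings(as.integer(head_tok[1L]))
  if (is.na(L) || L < 1L)
    stop("CT header must start with the sequence length: ", path, call. = FALSE)
  id <- if (length(head_tok) > 1L) paste(head_tok[-1L], collapse = " ") else
    sub("\\.ct$", "", basename(path))
  if (length(lines) < L + 1L)
    stop(sprintf("CT file %s: header says L = %d but only %d data lines",
                 path, L, length(lines) - 1L), call. = FALSE)
  bases <- character(L)
  partner <- integer(L)
  for (k in seq_len(L)) {
    tok <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1L]]
    if (length(tok) < 6L)
      stop(sprintf("CT line %d: expected 6 columns, got %d", k + 1L, length(tok)),
           call. = FALSE)
    i <- suppressWarnings(as.integer(tok[1L]))
    p <- suppressWarnings(as.integer(tok[5L]))
    if (is.na(i) || i != k)
      stop(sprintf("CT line %d: index column is not %d", k + 1L, k), call. = FALSE)
    if (is.na(p) || p < 0L || p > L)
      stop(sprintf("CT line %d: partner %s out of range [0, %d]", k + 1L,
                   tok[5L], L), call. = FALSE)
    bases[k] <- tok[2L]
    partner[k] <- p
  }
  for (k in seq_len(L)) {
    p <- partner[k]
    if (p > 0L && partner[p] != k)
      stop(sprintf("CT line %d: base %d says partner %d but base %d says %d",
                   p + 1L, k, p, p, partner[p]), call. = FALSE)
    if (p == k)
      stop(sprintf("CT line %d: base paired with itself", k + 1L), call. = FALSE)
  }
  prs <- which(partner > seq_len(L))
  pm <- pair_map(L, cbind(prs, partner[prs]))
  list(seq = rna_sequence(id, paste(bases, collapse = "")), pairs = pm)
}

#' Write a secondary structure in CT format
#'
#' Inverse of [read_ct()]: `read_ct(write_ct(seq, pm, path))` reproduces its
#' input exactly, including pseudoknotted (crossing) pair sets.
#'
#' @param seq an [rna_sequence()].
#' @param pm the matching [pair_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(seq, pm, path) {
  L <- length(seq)
  if (pm$length != L)
    stop("sequence length and pair map length disagree", call. = FALSE)
  partner <- partner_vector(pm)
  ch <- seq_chars(seq)
  lines <- c(sprintf("%d %s", L, seq$id),
             sprintf("%d %s %d %d %d %d", seq_len(L), ch, seq_len(L) - 1L,
                     ifelse(seq_len(L) == L, 0L, seq_len(L) + 1L),
                     partner, seq_len(L)))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a pair map to the L x L binary structure matrix
#'
#' Entry (i, j) is 1 exactly when bases i and j pair; the matrix is binary,
#' symmetric, has at most one 1 per row and column, and a zero band within
#' |i - j| < 4. Pseudoknots (crossing pairs) are representable without any
#' special handling.
#'
#' @param pm a [pair_map()].
#' @return An L x L 0/1 matrix.
#' @export
pairs_to_matrix <- function(pm) {
  stopifnot(inherits(pm, "pair_map"))
  S <- matrix(0, pm$length, pm$length)
  if (nrow(pm$pairs) > 0L) {
    S[pm$pairs] <- 1
    S[pm$pairs[, c(2L, 1L), drop = FALSE]] <- 1
  }
  S
}

#' Convert a structure matrix back to a pair map
#'
#' Inverse of [pairs_to_matrix()]. The matrix is audited first and a validity
#' error listing the violated constraints is raised if it is not a legal
#' structure matrix.
#'
#' @param S an L x L binary structure matrix.
#' @return A [pair_map()].
#' @export
matrix_to_pairs <- function(S) {
  v <- audit_validity(S)
  if (length(v) > 0L)
    stop("invalid structure matrix:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  idx <- which(S == 1 & upper.tri(S), arr.ind = TRUE)
  pair_map(nrow(S), idx)
}

# ---- dot-bracket -----------------------------------------------------------

BRACKET_OPEN <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

# TRUE if chord pairs a and b (rows c(i, j)) cross: i < k < j < l
pairs_cross <- function(a, b) {
  (a[1L] < b[1L] && b[1L] < a[2L] && a[2L] < b[2L]) ||
    (b[1L] < a[1L] && a[1L] < b[2L] && b[2L] < a[2L])
}

# indices (rows of `pairs`) of a maximum non-crossing subset, extracted with
# the same DP as the built-in folder restricted to the given chords
max_noncrossing_subset <- function(pairs, L) {
  allowed <- matrix(FALSE, L, L)
  allowed[pairs] <- TRUE
  sel <- nussinov_pairs_cpp(allowed[], 1L) + 1L  # back to 1-based
  if (nrow(sel) == 0L) return(integer(0))
  key <- paste(sel[, 1L], sel[, 2L])
  match(key, paste(pairs[, 1L], pairs[, 2L]))
}

#' Write a structure as dot-bracket text
#'
#' Pseudoknots are handled by tier decomposition: a maximum non-crossing
#' subset of the remaining pairs is extracted repeatedly, and each tier uses
#' the next bracket family from `()`, `[]`, `{}`, `<>`. Structures needing
#' more than four mutually crossing tiers cannot be written (use CT instead).
#'
#' @param seq an [rna_sequence()].
#' @param pm the matching [pair_map()].
#' @return A single dot-bracket string of length L.
#' @export
write_dotbracket <- function(seq, pm) {
  L <- length(seq)
  if (pm$length != L)
    stop("sequence length and pair map length disagree", call. = FALSE)
  out <- rep(".", L)
  remaining <- pm$pairs
  tier <- 0L
  while (nrow(remaining) > 0L) {
    tier <- tier + 1L
    if (tier > 4L)
      stop("structure needs more than 4 bracket tiers; write CT instead",
           call. = FALSE)
    take <- max_noncrossing_subset(remaining, L)
    sel <- remaining[take, , drop = FALSE]
    out[sel[, 1L]] <- BRACKET_OPEN[tier]
    out[sel[, 2L]] <- BRACKET_CLOSE[tier]
    remaining <- remaining[-take, , drop = FALSE]
  }
  paste(out, collapse = "")
}

#' Parse dot-bracket text
#'
#' Accepts all four bracket families `()`, `[]`, `{}`, `<>`; each family is
#' matched with its own stack, so crossing tiers (pseudoknots) round-trip.
#'
#' @param text a dot-bracket string.
#' @param bases optional base string of the same length; when given, the
#'   result carries an [rna_sequence()].
#' @param id identifier for the returned sequence.
#' @return A list with `pairs` ([pair_map()]) and, if `bases` was supplied,
#'   `seq`.
#' @export
parse_dotbracket <- function(text, bases = NULL, id = "seq") {
  ch <- strsplit(text, "")[[1L]]
  L <- length(ch)
  ok <- ch %in% c(".", BRACKET_OPEN, BRACKET_CLOSE)
  if (!all(ok))
    stop("invalid dot-bracket character: ", ch[!ok][1L], call. = FALSE)
  pairs <- NULL
  for (f in seq_along(BRACKET_OPEN)) {
    stack <- integer(0)
    for (k in seq_len(L)) {
      if (ch[k] == BRACKET_OPEN[f]) {
        stack <- c(stack, k)
      } else if (ch[k] == BRACKET_CLOSE[f]) {
        if (length(stack) == 0L)
          stop(sprintf("unbalanced '%s' at position %d", ch[k], k), call. = FALSE)
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L)
      stop(sprintf("unclosed '%s' at position %d", BRACKET_OPEN[f],
                   stack[length(stack)]), call. = FALSE)
  }
  res <- list(pairs = pair_map(L, pairs))
  if (!is.null(bases)) {
    if (nchar(bases) != L)
      stop("bases and dot-bracket text have different lengths", call. = FALSE)
    res$seq <- rna_sequence(id, bases)
  }
  res
}
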