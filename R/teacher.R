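# Knowledge merge: random sequences labelled by a deterministic "teacher"
# folding method become supplementary training samples, transferring the
# teacher's behaviour to the scoring network for out-of-family inputs.

#' Synthesize a random RNA sequence
#'
#' Length uniform on `[L1, L2]`, bases i.i.d. uniform over A, U, C, G.
#'
#' @param L1,L2 inclusive length bounds.
#' @param id identifier.
#' @return An [rna_sequence()].
#' @export
synthesize_sequence <- function(L1 = 50L, L2 = 500L, id = "synth") {
  stopifnot(L1 >= 1L, L1 <= L2)
  L <- if (L1 == L2) L1 else sample(L1:L2, 1L)
  rna_sequence(id, paste(random_bases(L), collapse = ""), normalize = FALSE)
}

# allowed-pair mask from sequence complementarity
complementarity_mask <- function(seq, allowed_pairs = CANONICAL_PAIRS) {
  ch <- seq_chars(seq)
  L <- length(ch)
  outer(ch, ch, function(a, b) paste0(a, b) %in% allowed_pairs)
}

#' Built-in base-pair-maximization folder
#'
#' A Nussinov-style dynamic program: finds a maximum-cardinality set of
#' non-crossing allowed pairs (canonical + wobble by default) with pair
#' separation `j - i >= min_sep`. The traceback is deterministic (prefer
#' pairing the left end, then the smallest partner), so the folder is a
#' total, deterministic mapping from sequences to valid structure matrices —
#' exactly the contract a knowledge-merge teacher must satisfy. The default
#' `min_sep = 4` matches the sharp-loop rule, so outputs are valid by
#' construction.
#'
#' @param seq an [rna_sequence()] or character string.
#' @param min_sep minimum pair separation `j - i`.
#' @param allowed_pairs character vector of allowed base-pair kinds.
#' @return An L x L binary structure matrix.
#' @export
nussinov_fold <- function(seq, min_sep = 4L,
                          allowed_pairs = CANONICAL_PAIRS) {
  seq <- as_rna_sequence(seq)
  mask <- complementarity_mask(seq, allowed_pairs)
  prs <- nussinov_pairs_cpp(mask, as.integer(min_sep)) + 1L
  pairs_to_matrix(pair_map(length(seq), prs))
}

#' Wrap a folding method as a teacher
#'
#' Accepts either an R function mapping an [rna_sequence()] to a structure
#' (a structure matrix, a [pair_map()], or a dot-bracket string), or a shell
#' command template containing `{fasta}`, which is replaced by the path of a
#' one-record FASTA file; the command must print a dot-bracket string (the
#' first line consisting only of dot-bracket characters is used — extra
#' annotation lines such as energies are ignored) or a CT table to standard
#' output. This is how external folders (LinearFold, RNAstructure,
#' RNAfold, ...) plug in; the test suite relies only on the built-in folder.
#'
#' Every teacher output is audited; an invalid or unparseable structure
#' raises a teacher error carrying the captured output.
#'
#' @param method an R function or a command template string.
#' @return A function `(rna_sequence) -> structure matrix` that always
#'   returns an audited valid structure.
#' @export
external_teacher <- function(method) {
  run <- if (is.function(method)) {
    method
  } else if (is.character(method) && length(method) == 1L) {
    if (!grepl("{fasta}", method, fixed = TRUE))
      stop("command template must contain {fasta}", call. = FALSE)
    function(seq) {
      fa <- tempfile(fileext = ".fa")
      on.exit(unlink(fa))
      write_fasta(seq, fa)
      cmd <- gsub("{fasta}", shQuote(fa), method, fixed = TRUE)
      out <- tryCatch(system(cmd, intern = TRUE),
                      warning = function(w) stop("teacher command failed: ",
                                                 cmd, call. = FALSE))
      out
    }
  } else {
    stop("method must be a function or a command template string",
         call. = FALSE)
  }
  function(seq) {
    seq <- as_rna_sequence(seq)
    raw <- run(seq)
    S <- teacher_output_to_matrix(raw, length(seq))
    v <- audit_validity(S)
    if (length(v) > 0L)
      stop("teacher produced an invalid structure:\n  ",
           paste(v, collapse = "\n  "), call. = FALSE)
    S
  }
}

# interpret a teacher's output (matrix / pair_map / dot-bracket / CT lines)
teacher_output_to_matrix <- function(raw, L) {
  if (is.matrix(raw)) {
    if (!all(dim(raw) == c(L, L)))
      stop(sprintf("teacher error: matrix output is %d x %d, expected %d x %d",
                   nrow(raw), ncol(raw), L, L), call. = FALSE)
    return(raw)
  }
  if (inherits(raw, "pair_map")) {
    if (raw$length != L)
      stop("teacher error: pair map length mismatch", call. = FALSE)
    return(pairs_to_matrix(raw))
  }
  if (is.character(raw)) {
    db <- grep("^[][(){}<>.]+$", trimws(raw), value = TRUE)
    if (length(db) > 0L) {
      if (nchar(db[1L]) != L)
        stop(sprintf("teacher error: dot-bracket output of length %d for a sequence of length %d (output: %s)",
                     nchar(db[1L]), L, db[1L]), call. = FALSE)
      return(pairs_to_matrix(parse_dotbracket(db[1L])$pairs))
    }
    # fall back to CT
    tf <- tempfile(fileext = ".ct")
    on.exit(unlink(tf))
    writeLines(raw, tf)
    ct <- tryCatch(read_ct(tf), error = function(e)
      stop("teacher error: unparseable output:\n", paste(raw, collapse = "\n"),
           call. = FALSE))
    if (ct$pairs$length != L)
      stop("teacher error: CT length mismatch", call. = FALSE)
    return(pairs_to_matrix(ct$pairs))
  }
  stop("teacher error: unsupported output type ", class(raw)[1L], call. = FALSE)
}

#' Generate a teacher-labelled synthetic training set
#'
#' Repeatedly synthesizes a random sequence and labels it with the teacher's
#' predicted structure, yielding "sequence-prediction" pairs that serve as
#' supplementary training samples. Defaults mirror the working setup for the
#' full-scale pipeline (lengths 50-500, 30,000 samples); tests and the
#' desk-scale experiments pass much smaller values.
#'
#' @param n number of samples.
#' @param L1,L2 length bounds for [synthesize_sequence()].
#' @param teacher a teacher function (see [external_teacher()]); defaults to
#'   the built-in [nussinov_fold()].
#' @param seed optional seed.
#' @return A list of [rna_sample()] objects with family tag `"synthetic"`.
#' @export
generate_teacher_set <- function(n = 30000L, L1 = 50L, L2 = 500L,
                                 teacher = nussinov_fold, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(k) {
    s <- synthesize_sequence(L1, L2, id = sprintf("synth_%05d", k))
    S <- teacher(s)
    rna_sample(s, S, family = "synthetic")
  })
}

#' Fraction of bases with identical predicted partners
#'
#' For each base, the predicted outcome is its partner index (or "unpaired");
#' the same-prediction ratio between two predictions is the fraction of the
#' L bases whose outcome agrees. Used to quantify how closely a model tracks
#' its knowledge-merge teacher.
#'
#' @param predA,predB two binary structure matrices of equal size.
#' @return A scalar in \[0, 1\].
#' @export
same_prediction_ratio <- function(predA, predB) {
  if (!all(dim(predA) == dim(predB)))
    stop("predictions must have equal lengths", call. = FALSE)
  pa <- partner_vector(matrix_to_pairs(predA))
  pb <- partner_vector(matrix_to_pairs(predB))
  mean(pa == pb)
}
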