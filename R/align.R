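# Local alignment (affine-gap Smith-Waterman) and scoring helpers. The
# dynamic program lives in src/align.cpp; this file handles alphabets,
# validation and the user-facing alignment object.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Nucleotide scoring matrix
#'
#' Simple match/mismatch scoring over `ACGT` plus `N` (scored 0 against
#' everything), the default for nucleotide-level searches.
#'
#' @param match,mismatch scores for identical / differing bases.
#' @return A 5x5 numeric matrix.
#' @export
nt_score_matrix <- function(match = 1, mismatch = -1) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

resolve_matrix <- function(matrix) {
  if (is.character(matrix) && length(matrix) == 1) {
    if (identical(matrix, "BLOSUM62")) return(blosum62_matrix())
    abort(sprintf("unknown score matrix '%s'", matrix))
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix))) {
    abort("`matrix` must be a named square score matrix or \"BLOSUM62\"")
  }
  matrix
}

encode_seq <- function(seq, alphabet, what) {
  v <- chars(seq)
  code <- match(v, alphabet)
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    abort(sprintf("non-standard residue '%s' at position %d of %s",
                  v[bad], bad, what))
  }
  code
}

#' Optimal local alignment with affine gap costs
#'
#' Smith-Waterman with gap cost `gap_open + L * gap_extend` for a gap of
#' length `L`. The traceback is deterministic (tie-break diagonal > up >
#' left). Intervals in the result are 0-based half-open.
#'
#' @param query,target sequences (protein by default; any alphabet covered by
#'   the score matrix).
#' @param matrix `"BLOSUM62"` or a named score matrix (see
#'   [nt_score_matrix()] for nucleotide work).
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @return An object of class `local_alignment` with elements `score`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `q_aln`, `t_aln`, `length`
#'   (aligned columns) and `percent_identity` (matches over aligned columns,
#'   gap columns counting as mismatches).
#' @export
local_align <- function(query, target, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  S <- resolve_matrix(matrix)
  ab <- rownames(S)
  if (nchar(query) == 0 || nchar(target) == 0) {
    abort("`query` and `target` must be non-empty")
  }
  q <- encode_seq(query, ab, "`query`")
  t <- encode_seq(target, ab, "`target`")
  raw <- .sw_align(q, t, S, gap_open, gap_extend, TRUE)
  decode <- function(code) {
    paste(ifelse(code == 0, "-", ab[pmax(code, 1L)]), collapse = "")
  }
  qa <- if (length(raw$q_aln)) decode(raw$q_aln) else ""
  ta <- if (length(raw$t_aln)) decode(raw$t_aln) else ""
  len <- nchar(qa)
  pid <- if (len == 0) NA_real_ else {
    100 * sum(chars(qa) == chars(ta) & chars(qa) != "-") / len
  }
  structure(list(
    score = raw$score,
    q_start = raw$q_start, q_end = raw$q_end,
    t_start = raw$t_start, t_end = raw$t_end,
    q_aln = qa, t_aln = ta,
    length = len, percent_identity = pid
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> score %.1f, %d columns, %.1f%% identity\n",
              x$score, x$length, x$percent_identity %||% NA_real_))
  cat(sprintf("  query  [%d, %d): %s\n", x$q_start, x$q_end, x$q_aln))
  cat(sprintf("  target [%d, %d): %s\n", x$t_start, x$t_end, x$t_aln))
  invisible(x)
}

#' Convert a raw alignment score to bits
#'
#' Karlin-Altschul normalisation, with the classic ungapped BLOSUM62
#' parameters as defaults. Used as the sensitivity floor of the relaxed
#' translated search (a deterministic stand-in for an E-value cut-off, which
#' is not meaningful on desk-scale databases).
#'
#' @param score raw alignment score.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Score in bits.
#' @export
bit_score <- function(score, lambda = 0.267, K = 0.041) {
  (lambda * score - log(K)) / log(2)
}

# global (Needleman-Wunsch) nucleotide alignment via Biostrings, returning
# the two aligned strings
global_align_nt <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 2) {
  sub <- nt_score_matrix(match, mismatch)[1:4, 1:4]
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sub, gapOpening = gap_open, gapExtension = gap_extend
  )
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}
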