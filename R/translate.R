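#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 start at positions 1..3 of the sequence; frames -1..-3 start
#' at positions 1..3 of the reverse complement. Trailing partial codons are
#' dropped, codons containing `N` translate to `X`, and stop codons are `*`.
#'
#' @param seq nucleotide string over `ACGTN` (case-insensitive).
#' @return Tibble with columns `frame` (1, 2, 3, -1, -2, -3) and `protein`.
#' @export
translate_six_frames <- function(seq) {
  seq <- toupper(seq)
  bad <- setdiff(unique(chars(seq)), c(DNA_BASES, "N"))
  if (length(bad) > 0) {
    abort(sprintf("sequence contains non-ACGTN symbol '%s'", bad[1]))
  }
  code <- Biostrings::GENETIC_CODE
  one_frame <- function(s, off) {
    n <- nchar(s) - off
    n <- n - n %% 3
    if (n <= 0) return("")
    starts <- seq(off + 1, off + n, by = 3)
    codons <- substring(s, starts, starts + 2)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"          # codons containing N
    paste(aa, collapse = "")
  }
  rc <- if (nchar(seq) > 0) revcomp(seq) else ""
  tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    protein = c(one_frame(seq, 0), one_frame(seq, 1), one_frame(seq, 2),
                one_frame(rc, 0), one_frame(rc, 1), one_frame(rc, 2))
  )
}

# open reading frames (stop-to-stop segments; no start-codon requirement) of
# at least min_aa residues, across all six frames; longest first
orf_candidates <- function(seq, min_aa) {
  frames <- translate_six_frames(seq)
  out <- list()
  for (i in seq_len(nrow(frames))) {
    segs <- strsplit(frames$protein[i], "*", fixed = TRUE)[[1]]
    segs <- segs[nchar(segs) >= min_aa]
    if (length(segs) > 0) {
      out[[length(out) + 1]] <- tibble(frame = frames$frame[i], orf = segs)
    }
  }
  if (length(out) == 0) return(tibble(frame = integer(0), orf = character(0)))
  arrange(bind_rows(out), dplyr::desc(nchar(.data$orf)), .data$frame)
}
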