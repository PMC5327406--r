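# Position-specific scoring: a log-odds PSSM built from an ungapped block of
# reference sequences, scanned along a target. A deliberately simple stand-in
# for profile HMM searches: no insert/delete states (see Non-goals in the
# methods vignette).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a log-odds position weight matrix from an ungapped block
#'
#' Column probabilities are estimated with a pseudocount and converted to
#' log2 odds against a uniform background over the 20 amino acids.
#'
#' @param block character vector of equal-length, gap-free protein sequences.
#' @param pseudocount added to every residue count per column.
#' @return A 20 x W numeric matrix of log2 odds, rows named by residue,
#'   class `pssm`.
#' @export
pssm_build <- function(block, pseudocount = 0.5) {
  if (length(block) == 0) abort("`block` must contain at least one sequence")
  w <- unique(nchar(block))
  if (length(w) != 1) abort("block sequences must have equal length")
  mats <- do.call(rbind, strsplit(toupper(block), ""))
  bad <- setdiff(unique(as.vector(mats)), AA20)
  if (length(bad) > 0) {
    abort(sprintf("block contains non-standard residue '%s'", bad[1]))
  }
  counts <- apply(mats, 2, function(col) {
    table(factor(col, levels = AA20))
  })
  probs <- (counts + pseudocount) / (length(block) + 20 * pseudocount)
  m <- log2(probs / (1 / 20))
  rownames(m) <- AA20
  structure(m, class = c("pssm", class(m)))
}

#' Scan a protein sequence with a PSSM
#'
#' Scores every window of the profile's width as the sum of per-column
#' log-odds; windows at or above `min_score` are returned sorted by score
#' (descending), then position.
#'
#' @param profile a [pssm_build()] matrix.
#' @param target protein sequence; residues outside the 20-letter alphabet
#'   (e.g. `X`) contribute the column minimum.
#' @param min_score score threshold.
#' @return Tibble with columns `position` (1-based window start) and `score`.
#' @export
pssm_scan <- function(profile, target, min_score = 0) {
  w <- ncol(profile)
  n <- nchar(target)
  if (n < w) return(tibble(position = integer(0), score = numeric(0)))
  v <- chars(toupper(target))
  idx <- match(v, rownames(profile))
  col_min <- apply(profile, 2, min)
  scores <- vapply(seq_len(n - w + 1), function(s) {
    cols <- seq_len(w)
    ii <- idx[s + cols - 1]
    sum(ifelse(is.na(ii), col_min[cols], profile[cbind(ii, cols)]))
  }, numeric(1))
  hits <- tibble(position = seq_len(n - w + 1), score = scores) |>
    filter(.data$score >= min_score) |>
    arrange(dplyr::desc(.data$score), .data$position)
  hits
}
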