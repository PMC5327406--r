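#' Greedy overlap assembly of a read set
#'
#' Repeatedly merges the pair of sequences with the best suffix-prefix
#' overlap (identity first, then overlap length, then lexicographic ids) of
#' at least `min_overlap` nt and at least `min_identity`, until no pair
#' qualifies. Mismatched positions in an overlap take the base of the
#' left-hand sequence. Reads are taken as given (single-stranded); reverse
#' complements are not considered.
#'
#' @param reads character vector of read sequences (optionally named by read
#'   id) or a tibble with columns `read_id` and `seq`.
#' @param min_overlap minimum overlap length in nt (>= 1).
#' @param min_identity minimum overlap identity in `[0, 1]`.
#' @return Tibble with columns `contig_id`, `seq`, `n_reads`, ordered by
#'   contig id.
#' @export
greedy_assemble <- function(reads, min_overlap = 20, min_identity = 0.97) {
  if (min_overlap < 1) abort("`min_overlap` must be >= 1")
  if (is.data.frame(reads)) {
    ids <- reads$read_id; seqs <- reads$seq
  } else {
    seqs <- unname(reads)
    ids <- names(reads) %||% sprintf("read_%d", seq_along(reads))
  }
  if (length(seqs) == 0) {
    return(tibble(contig_id = character(0), seq = character(0),
                  n_reads = integer(0)))
  }
  ord <- order(ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  n_reads <- rep(1L, length(seqs))

  pair_overlap <- function(a, b) {
    ov <- .best_overlap(a, b, as.integer(min_overlap))
    if (ov[1] == 0) return(c(0, -1))
    id <- ov[2] / ov[1]
    if (id < min_identity) return(c(0, -1))
    c(ov[1], id)
  }

  # cached qualifying-overlap matrices; only the merged row/column is
  # recomputed after each merge
  k <- length(seqs)
  ov_len <- matrix(0L, k, k)
  ov_id <- matrix(-1, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b) {
      ov <- pair_overlap(seqs[a], seqs[b])
      ov_len[a, b] <- ov[1]; ov_id[a, b] <- ov[2]
    }
  }

  repeat {
    k <- length(seqs)
    if (k < 2 || max(ov_id) < 0) break
    top <- max(ov_id)
    cand <- which(ov_id == top, arr.ind = TRUE)
    lens <- ov_len[cand]
    cand <- cand[lens == max(lens), , drop = FALSE]
    if (nrow(cand) > 1) {
      keys <- paste(ids[cand[, 1]], ids[cand[, 2]])
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    best <- c(cand[1, 1], cand[1, 2])
    a <- best[1]; b <- best[2]
    merged <- paste0(seqs[a],
                     substr(seqs[b], ov_len[a, b] + 1, nchar(seqs[b])))
    merged_id <- min(ids[a], ids[b])
    merged_n <- n_reads[a] + n_reads[b]
    keep <- setdiff(seq_len(k), c(a, b))
    ids <- c(ids[keep], merged_id)
    seqs <- c(seqs[keep], merged)
    n_reads <- c(n_reads[keep], merged_n)
    m <- length(seqs)
    ov_len2 <- matrix(0L, m, m); ov_id2 <- matrix(-1, m, m)
    if (length(keep) > 0) {
      ov_len2[seq_along(keep), seq_along(keep)] <-
        ov_len[keep, keep, drop = FALSE]
      ov_id2[seq_along(keep), seq_along(keep)] <-
        ov_id[keep, keep, drop = FALSE]
    }
    ov_len <- ov_len2; ov_id <- ov_id2
    for (x in seq_len(m - 1)) {
      ov <- pair_overlap(seqs[x], seqs[m])
      ov_len[x, m] <- ov[1]; ov_id[x, m] <- ov[2]
      ov <- pair_overlap(seqs[m], seqs[x])
      ov_len[m, x] <- ov[1]; ov_id[m, x] <- ov[2]
    }
  }
  ord <- order(ids)
  tibble(contig_id = ids[ord], seq = seqs[ord], n_reads = n_reads[ord])
}
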