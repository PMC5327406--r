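# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# split a string into a character vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# integer encoding of a nucleotide string (A=1, C=2, G=3, T=4); names sites
# of offending symbols in the error message
encode_dna <- function(seq, what = "sequence") {
  v <- chars(seq)
  code <- match(v, DNA_BASES)
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    abort(sprintf("non-ACGT symbol '%s' at site %d of %s", v[bad], bad, what))
  }
  code
}

decode_dna <- function(code) paste(DNA_BASES[code], collapse = "")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

revcomp <- function(seq) {
  paste(rev(chars(chartr("ACGTN", "TGCAN", seq))), collapse = "")
}

# set of all k-mers of a string (used for seed-and-extend prefilters)
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1), k:n))
}

shares_kmer <- function(a_kmers, b, k) {
  n <- nchar(b)
  if (n < k) return(FALSE)
  any(substring(b, seq_len(n - k + 1), k:n) %in% a_kmers)
}

# which of many sequences share at least one k-mer with the given set
# (vectorised across all sequences at once)
which_share_kmer <- function(a_kmers, seqs, k) {
  counts <- pmax(nchar(seqs) - k + 1L, 0L)
  if (sum(counts) == 0) return(logical(length(seqs)))
  idx <- rep(seq_along(seqs), counts)
  starts <- sequence(counts)
  subs <- substring(seqs[idx], starts, starts + k - 1L)
  hit <- subs %in% a_kmers
  seq_along(seqs) %in% unique(idx[hit])
}

# fraction of differing sites between equal-length strings
hamming_frac <- function(a, b) .hamming(a, b) / nchar(a)

# JC69 distance from a mismatch fraction; Inf at/beyond saturation
jc69_distance <- function(p) {
  ifelse(p >= 0.75, Inf, -0.75 * log(1 - 4 * p / 3))
}

# expected mismatch fraction at JC69 distance t
jc69_p <- function(t) 0.75 * (1 - exp(-4 * t / 3))

`%||%` <- rlang::`%||%`

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}
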