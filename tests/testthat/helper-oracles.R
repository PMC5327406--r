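# Independent oracles used by the test-suite: brute-force enumeration
# implementations that share no code with the package's algorithms.

# --- local alignment oracle -------------------------------------------------
# Enumerates every monotone matching of query/target positions; the affine
# cost of the gaps between consecutive matched pairs is open + len * extend
# per gap run. Feasible for lengths <= 7.
bf_local_align <- function(q, t, S, gap_open, gap_extend) {
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(t, "")[[1]]
  n <- length(qv); m <- length(tv)
  subsets <- function(k) {
    if (k == 0) return(list(integer(0)))
    unlist(lapply(0:(2^k - 1), function(mask) {
      list(which(bitwAnd(mask, 2^(0:(k - 1))) > 0))
    }), recursive = FALSE)
  }
  qs <- subsets(n); ts <- subsets(m)
  best <- 0
  for (a in qs) {
    k <- length(a)
    if (k == 0) next
    for (b in ts) {
      if (length(b) != k) next
      sc <- sum(S[cbind(qv[a], tv[b])])
      if (k > 1) {
        da <- diff(a) - 1L; db <- diff(b) - 1L
        sc <- sc - sum(ifelse(da > 0, gap_open + da * gap_extend, 0)) -
          sum(ifelse(db > 0, gap_open + db * gap_extend, 0))
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# --- Fitch parsimony oracle -------------------------------------------------
# Minimum number of state changes over all assignments of internal nodes.
bf_fitch_cost <- function(tree, tip_states, alphabet) {
  ntip <- length(tree$tip.label)
  internals <- (ntip + 1):(ntip + tree$Nnode)
  grid <- expand.grid(rep(list(alphabet), length(internals)),
                      stringsAsFactors = FALSE)
  state_of <- function(v, assignment) {
    if (v <= ntip) tip_states[[v]] else assignment[[match(v, internals)]]
  }
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assignment <- as.character(grid[r, ])
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      sp <- state_of(tree$edge[e, 1], assignment)
      sc <- state_of(tree$edge[e, 2], assignment)
      # a tip with missing data matches anything at zero cost
      if (length(sc) > 1) next
      if (length(sp) > 1) next
      if (sp != sc) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

# --- pruning likelihood oracle ----------------------------------------------
# Exhaustive sum over internal-node states; JC69 only.
bf_loglik_jc69 <- function(tree, aln) {
  p_ij <- function(t, same) {
    pd <- 0.25 * (1 - exp(-4 * t / 3))
    if (same) 1 - 3 * pd else pd
  }
  ntip <- length(tree$tip.label)
  internals <- (ntip + 1):(ntip + tree$Nnode)
  seqs <- strsplit(aln$seq[match(tree$tip.label, aln$id)], "")
  nsites <- length(seqs[[1]])
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (s in seq_len(nsites)) {
    tipstate <- vapply(seqs, `[`, character(1), s)
    grid <- expand.grid(rep(list(bases), length(internals)),
                        stringsAsFactors = FALSE)
    lik <- 0
    for (r in seq_len(nrow(grid))) {
      assignment <- as.character(grid[r, ])
      state_of <- function(v) {
        if (v <= ntip) tipstate[v] else assignment[match(v, internals)]
      }
      term <- 0.25
      for (e in seq_len(nrow(tree$edge))) {
        term <- term * p_ij(tree$edge.length[e],
                            state_of(tree$edge[e, 1]) ==
                              state_of(tree$edge[e, 2]))
      }
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# --- misc -------------------------------------------------------------------
random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# per-codon translation oracle independent of the package implementation
codon_oracle <- local({
  tab <- NULL
  function(seq) {
    if (is.null(tab)) {
      b <- c("T", "C", "A", "G")
      aa <- strsplit(paste0(
        "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
      codons <- unlist(lapply(b, function(x)
        unlist(lapply(b, function(y) paste0(x, y, b)))))
      tab <<- setNames(aa, codons)
    }
    n <- nchar(seq) - nchar(seq) %% 3
    if (n == 0) return("")
    starts <- seq(1, n, 3)
    cods <- substring(seq, starts, starts + 2)
    out <- unname(tab[cods])
    out[is.na(out)] <- "X"
    paste(out, collapse = "")
  }
})

revcomp_oracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}
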