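# Sequence evolution primitives of the simulator (substitutions only; the
# generator is deliberately indel-free so downstream alignment is trivial).

# K80 substitution probabilities at distance t (expected substitutions/site)
# with transition/transversion rate ratio kappa; returns c(ts, tv) where tv is
# the probability of EACH of the two transversions.
k80_probs <- function(t, kappa) {
  e1 <- exp(-4 * t / (kappa + 2))
  e2 <- exp(-2 * t * (kappa + 1) / (kappa + 2))
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv <- 0.25 - 0.25 * e1
  c(ts = ts, tv = tv)
}

#' Evolve a nucleotide sequence for a given expected number of substitutions
#'
#' Applies independent per-site substitutions under JC69 or K80. Under JC69
#' each site changes with probability \eqn{3/4 (1 - e^{-4t/3})} and the new
#' base is uniform over the three alternatives; under K80 transitions and
#' transversions have their model probabilities at distance `t_eff`.
#'
#' @param seq nucleotide string over `ACGT`.
#' @param t_eff expected substitutions per site (branch length times the
#'   gene's effective rate); must be >= 0.
#' @param model `"JC69"` or `"K80"`.
#' @param kappa K80 transition/transversion rate ratio.
#' @return The evolved sequence (same length).
#' @export
evolve_sequence <- function(seq, t_eff, model = c("JC69", "K80"), kappa = 2) {
  model <- match.arg(model)
  if (!is.numeric(t_eff) || length(t_eff) != 1 || is.na(t_eff) || t_eff < 0) {
    abort("`t_eff` must be a single number >= 0")
  }
  x <- encode_dna(seq, "`seq`")
  if (length(x) == 0 || t_eff == 0) return(seq)
  decode_dna(evolve_codes(x, t_eff, model, kappa))
}

# integer-coded workhorse of evolve_sequence (codes 1..4 = A,C,G,T)
evolve_codes <- function(x, t_eff, model, kappa = 2) {
  n <- length(x)
  if (n == 0 || t_eff == 0) return(x)
  if (model == "JC69") {
    p <- jc69_p(t_eff)
    flip <- runif(n) < p
    k <- sum(flip)
    if (k > 0) {
      # other three bases, uniformly
      others <- matrix(c(2L, 3L, 4L,  1L, 3L, 4L,  1L, 2L, 4L,  1L, 2L, 3L),
                       nrow = 4, byrow = TRUE)
      pick <- sample.int(3L, k, replace = TRUE)
      x[flip] <- others[cbind(x[flip], pick)]
    }
  } else {
    pr <- k80_probs(t_eff, kappa)
    u <- runif(n)
    ts_partner <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
    tv1 <- c(2L, 1L, 2L, 1L)                 # a pyrimidine/purine partner
    tv2 <- c(4L, 3L, 4L, 3L)                 # the other transversion
    is_ts <- u < pr["ts"]
    is_tv1 <- !is_ts & u < pr["ts"] + pr["tv"]
    is_tv2 <- !is_ts & !is_tv1 & u < pr["ts"] + 2 * pr["tv"]
    x[is_ts] <- ts_partner[x[is_ts]]
    x[is_tv1] <- tv1[x[is_tv1]]
    x[is_tv2] <- tv2[x[is_tv2]]
  }
  x
}

#' Invert an interval of a signed gene order
#'
#' Reverses the rows `i..j` of a signed gene order and flips their strands;
#' genes outside the interval are untouched. Applying the same inversion twice
#' restores the original order.
#'
#' @param order tibble with columns `gene` and `strand` (`+`/`-`), in order.
#' @param i,j 1-based inclusive interval bounds, `1 <= i <= j <= nrow(order)`.
#' @return The rearranged signed gene order.
#' @export
apply_inversion <- function(order, i, j) {
  order <- as_tibble(order)
  n <- nrow(order)
  if (!is.numeric(i) || !is.numeric(j) || i < 1 || j > n || i > j) {
    abort(sprintf("invalid inversion interval [%s, %s] for %d genes",
                  format(i), format(j), n))
  }
  idx <- seq(i, j)
  flipped <- order[rev(idx), ]
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  order[idx, ] <- flipped
  order
}

#' Fragment a sequence into error-bearing shotgun reads
#'
#' Draws `ceiling(coverage * length / read_len)` reads at uniform random start
#' positions; each base is substituted by a uniformly chosen different base
#' with probability `err_rate`. Qualities are constant.
#'
#' @param seq source nucleotide sequence.
#' @param coverage fold coverage (> 0).
#' @param read_len read length in nt; must not exceed the sequence length.
#' @param err_rate per-base error probability.
#' @param id_prefix prefix for read ids.
#' @return Tibble with columns `read_id`, `seq`, `qual`, `start`.
#' @export
fragment_reads <- function(seq, coverage, read_len, err_rate = 0,
                           id_prefix = "read") {
  n <- nchar(seq)
  if (read_len > n) abort("`read_len` exceeds the sequence length")
  if (coverage <= 0) abort("`coverage` must be > 0")
  n_reads <- ceiling(coverage * n / read_len)
  starts <- sample.int(n - read_len + 1L, n_reads, replace = TRUE)
  reads <- substring(seq, starts, starts + read_len - 1L)
  if (err_rate > 0) {
    mat <- do.call(rbind, lapply(reads, function(r) match(chars(r), DNA_BASES)))
    hit <- matrix(runif(length(mat)) < err_rate, nrow = nrow(mat))
    k <- sum(hit)
    if (k > 0) {
      others <- matrix(c(2L, 3L, 4L,  1L, 3L, 4L,  1L, 2L, 4L,  1L, 2L, 3L),
                       nrow = 4, byrow = TRUE)
      pick <- sample.int(3L, k, replace = TRUE)
      mat[hit] <- others[cbind(mat[hit], pick)]
      reads <- apply(mat, 1, function(row) paste(DNA_BASES[row], collapse = ""))
    }
  }
  tibble(
    read_id = sprintf("%s_%d", id_prefix, seq_len(n_reads)),
    seq = as.character(reads),
    qual = strrep("I", read_len),
    start = as.integer(starts)
  )
}
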