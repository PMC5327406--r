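# Alignment statistics, Fitch ancestors and substitution mapping.

test_that("strip_gap_columns implements both trimming modes", {
  aln <- aligned_set(c("a", "b", "c", "d", "e"),
                     c("ACDEF-GHIK",
                       "ACDEFLGH-K",
                       "ACDEFLGHIK",
                       "ACDEFLGHIK",
                       "ACD-FLGHIK"), "protein")
  any_gap <- strip_gap_columns(aln, "any_gap")
  expect_equal(nchar(any_gap$seq[1]), 7)                  # 3 gapped columns
  maj <- strip_gap_columns(aln, "majority_gap")
  expect_equal(nchar(maj$seq[1]), 10)                      # none > 50% gapped
  # all-gap column removed under both modes
  aln2 <- aligned_set(c("a", "b"), c("A-C", "A-C"), "protein")
  expect_equal(nchar(strip_gap_columns(aln2, "majority_gap")$seq[1]), 2)
  # gap-free alignment unchanged
  aln3 <- aligned_set(c("a", "b"), c("AC", "AC"), "protein")
  expect_equal(strip_gap_columns(aln3)$seq, aln3$seq)
  # everything removed: empty with warning
  aln4 <- aligned_set(c("a", "b"), c("-A", "A-"), "protein")
  expect_warning(out <- strip_gap_columns(aln4, "any_gap"), "empty")
  expect_equal(nchar(out$seq[1]), 0)
})

test_that("percent identity and similarity behave and bound each other", {
  expect_equal(percent_identity("AAAA", "AAAA"), 100)
  expect_equal(percent_identity("AAAA", "AAAT"), 75)
  expect_true(is.na(percent_identity("--", "AA")))
  # L<->I is conservative under BLOSUM62: similarity but not identity
  expect_equal(percent_identity("AL", "AI"), 50)
  expect_equal(percent_similarity("AL", "AI"), 100)
  # identical sequences: both 100
  expect_equal(percent_similarity("WYW", "WYW"), 100)
  # similarity >= identity for random pairs; both symmetric
  set.seed(81)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    a <- paste(sample(aa, 40, TRUE), collapse = "")
    b <- paste(sample(aa, 40, TRUE), collapse = "")
    expect_gte(percent_similarity(a, b), percent_identity(a, b))
    expect_equal(percent_identity(a, b), percent_identity(b, a))
    expect_equal(percent_similarity(a, b), percent_similarity(b, a))
  }
})

test_that("identity after simulated divergence matches the JC69 closed form", {
  set.seed(82)
  s <- random_dna_str(20000)
  t <- evolve_sequence(s, 0.1)
  id_exp <- 100 * (1 - 0.75 * (1 - exp(-0.4 / 3)))
  tol <- 3 * 100 * sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(percent_identity(s, t) - id_exp), tol)
})

test_that("Fitch reconstruction resolves textbook cases deterministically", {
  tree <- ape::read.tree(text = "((a:1,b:1)n1:1,(c:1,d:1)n2:1)root;")
  # unanimity
  aln <- aligned_set(c("a", "b", "c", "d"), c("A", "A", "A", "A"),
                     "nucleotide")
  anc <- reconstruct_ancestor(aln, tree, "root")
  expect_equal(anc$sequence, "A")
  expect_equal(anc$cost, 0)
  # (A,A,B,B): candidate set {A,B}, frequency tie, resolved alphabetically
  aln2 <- aligned_set(c("a", "b", "c", "d"), c("A", "A", "C", "C"),
                      "nucleotide")
  anc2 <- reconstruct_ancestor(aln2, tree, "root")
  expect_equal(anc2$sequence, "A")
  expect_equal(anc2$cost, 1)
  expect_equal(anc2$ambiguous, 1L)
  # protein tie-break by summed BLOSUM62 similarity: candidates {L, I} with
  # tips L, I, plus V,V below; V scores higher with I/L... pick documented
  aln3 <- aligned_set(c("a", "b", "c", "d"), c("L", "I", "L", "I"),
                      "protein")
  anc3 <- reconstruct_ancestor(aln3, tree, "root")
  expect_equal(anc3$sequence, "I")   # BLOSUM62: I vs {L,I,L,I} = 2+4+2+4 > L
  expect_error(reconstruct_ancestor(aln2, tree, "a"), "internal")
  expect_error(
    reconstruct_ancestor(aligned_set("a", "A", "nucleotide"), tree, "root"),
    "missing"
  )
})

test_that("Fitch cost equals the exhaustive minimum on trees up to 6 tips", {
  set.seed(83)
  bases <- c("A", "C", "G", "T")
  for (i in 1:40) {
    ntip <- sample(3:6, 1)
    tree <- ape::rtree(ntip, tip.label = paste0("t", 1:ntip))
    states <- sample(bases, ntip, TRUE)
    aln <- aligned_set(tree$tip.label, states, "nucleotide")
    anc <- reconstruct_ancestor(aln, tree, ntip + 1L)
    oracle <- bf_fitch_cost(tree, as.list(states), bases)
    expect_equal(anc$cost, oracle, label = paste("case", i))
  }
})

test_that("map_substitutions labels columns against BLOSUM62", {
  m <- map_substitutions("LLLL", "LDI-")
  expect_equal(m$label, c("identical", "nonconservative", "conservative",
                          "indel"))
  # identical pair
  m2 <- map_substitutions("ACDE", "ACDE")
  expect_true(all(m2$label == "identical"))
  # both-gap columns are skipped with a warning and labels partition the rest
  expect_warning(m3 <- map_substitutions("A-C", "A-C"), "skipped")
  expect_equal(nrow(m3), 2)
  expect_equal(sum(table(m3$label)), 2)
})

test_that("higher rate multipliers yield more non-identical columns", {
  set.seed(84)
  n <- 2000
  anc <- random_dna_str(n)
  frac_changed <- function(rho) {
    mean(vapply(1:10, function(i) {
      d <- evolve_sequence(anc, 0.05 * rho)
      m <- map_substitutions(anc, d, nt_score_matrix())
      mean(m$label != "identical")
    }, numeric(1)))
  }
  expect_lt(frac_changed(1), frac_changed(3))
  expect_lt(frac_changed(3), frac_changed(6))
})
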