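# Likelihood machinery, root-to-tip distances, and the normality-gated
# group comparison.

test_that("pruning likelihood reproduces closed forms", {
  # one site, two tips, identical states, zero branches: log(1/4)
  tree <- ape::read.tree(text = "(a:0,b:0);")
  aln <- aligned_set(c("a", "b"), c("A", "A"), "nucleotide")
  expect_equal(pruning_loglik(tree, aln), log(0.25))

  # pulley principle: likelihood invariant to root placement along a branch
  set.seed(91)
  s <- random_dna_str(500)
  seqs <- c(a = evolve_sequence(s, 0.1), b = evolve_sequence(s, 0.2),
            c = evolve_sequence(s, 0.15))
  aln3 <- aligned_set(names(seqs), unname(seqs), "nucleotide")
  t1 <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,c:0.1);")
  t2 <- ape::read.tree(text = "((a:0.1,b:0.2):0.01,c:0.14);")
  t3 <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,c:0.0);")
  expect_equal(pruning_loglik(t1, aln3), pruning_loglik(t2, aln3))
  expect_equal(pruning_loglik(t1, aln3), pruning_loglik(t3, aln3))

  expect_error(pruning_loglik(t1, aligned_set("a", "", "nucleotide")),
               "missing|zero")
})

test_that("pruning equals the exhaustive state-sum oracle (4 tips, 3 sites)", {
  set.seed(92)
  for (i in 1:8) {
    tree <- ape::rtree(4, tip.label = c("a", "b", "c", "d"))
    tree$edge.length <- runif(nrow(tree$edge), 0.01, 0.8)
    seqs <- vapply(1:4, function(j) random_dna_str(3), character(1))
    aln <- aligned_set(c("a", "b", "c", "d"), seqs, "nucleotide")
    expect_equal(pruning_loglik(tree, aln), bf_loglik_jc69(tree, aln),
                 tolerance = 1e-10)
  }
})

test_that("two-taxon ML branch lengths recover the JC69 closed form to 1e-6", {
  set.seed(93)
  s <- random_dna_str(4000)
  t <- evolve_sequence(s, 0.15)
  aln <- aligned_set(c("a", "b"), c(s, t), "nucleotide")
  topo <- ape::read.tree(text = "(a:0.1,b:0.1);")
  fit <- fit_branch_lengths(topo, aln, brent_tol = 1e-10)
  p_hat <- mean(strsplit(s, "")[[1]] != strsplit(t, "")[[1]])
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * p_hat / 3),
               tolerance = 1e-6)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  s <- strrep("ACGT", 100)
  aln <- aligned_set(c("a", "b", "c"), c(s, s, s), "nucleotide")
  topo <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  fit <- fit_branch_lengths(topo, aln)
  expect_true(all(fit$tree$edge.length < 1e-6))
})

test_that("the log-likelihood never decreases across sweeps", {
  set.seed(94)
  s <- random_dna_str(800)
  tree <- default_bird_tree()
  seqs <- vapply(tree$tip.label, function(sp) evolve_sequence(s, 0.2),
                 character(1))
  aln <- aligned_set(tree$tip.label, unname(seqs), "nucleotide")
  fit <- fit_branch_lengths(tree, aln)
  expect_true(all(diff(fit$logliks) >= -1e-9))
  expect_true(fit$converged)
  expect_equal(fit$loglik, pruning_loglik(fit$tree, aln))
  # and the likelihood at the fitted lengths matches an independent
  # phylogenetics library
  pd <- phangorn::phyDat(t(vapply(aln$seq, function(s) strsplit(s, "")[[1]],
                                  character(nchar(aln$seq[1])))),
                         type = "DNA")
  names(pd) <- aln$id
  expect_equal(fit$loglik, phangorn::pml(fit$tree, pd)$logLik,
               tolerance = 1e-6)
})

test_that("root_to_tip sums path lengths and is additive", {
  tree <- ape::read.tree(text = "(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:0.4)r;")
  expect_equal(root_to_tip(tree, "d"), 0.4)
  expect_equal(root_to_tip(tree, "a"), 0.3)
  expect_error(root_to_tip(tree, "zz"), "unknown")
  # lengthening one branch on the path adds exactly delta
  tree2 <- tree
  e <- which(tree2$edge[, 2] == match("a", tree2$tip.label))
  tree2$edge.length[e] <- tree2$edge.length[e] + 0.05
  expect_equal(root_to_tip(tree2, "a"), root_to_tip(tree, "a") + 0.05)
  # ingroup reference excludes the outgroup stem
  expect_equal(root_to_tip(tree, "a", "ingroup", outgroup = "d"), 0.2)
  expect_error(root_to_tip(tree, "d", "ingroup", outgroup = "d"),
               "outgroup")
})

test_that("a clade-specific rate multiplier inflates root-to-tip as expected", {
  cfg <- small_config(95, length_nt = 3000, p_loss = 0, p_salvage = 1,
                      rho = 3, interval = c(5, 5))
  sim <- simulate_locus(cfg)
  g <- cfg$locus$gene[5]
  alignments <- lapply(setNames(cfg$locus$gene[4:5], cfg$locus$gene[4:5]),
                       function(gg) {
    sq <- dplyr::filter(sim$sequences, gene == gg)
    aligned_set(sq$species, sq$seq, "nucleotide")
  })
  rt <- rate_table(alignments, sim$tree, cfg$outgroup)
  expected <- truth_root_to_tip(sim)
  joined <- dplyr::left_join(tibble::as_tibble(rt), expected,
                             by = c("gene", "species"))
  # affected tips of the boosted gene vs the neighbouring unboosted gene
  for (sp in c("chicken", "quail")) {
    obs_ratio <- joined$root_to_tip[joined$gene == g &
                                      joined$species == sp] /
      joined$root_to_tip[joined$gene == cfg$locus$gene[4] &
                           joined$species == sp]
    exp_ratio <- joined$expected_root_to_tip[joined$gene == g &
                                               joined$species == sp] /
      joined$expected_root_to_tip[joined$gene == cfg$locus$gene[4] &
                                    joined$species == sp]
    expect_lt(abs(obs_ratio - exp_ratio) / exp_ratio, 0.25)
  }
})

test_that("the omnibus normality test matches the frozen reference values", {
  # expected values computed once with an independent reference
  # implementation of the D'Agostino-Pearson omnibus test on the same
  # seeded samples, frozen here
  expected <- list(
    c(8.122105725512, 1.72308678226e-02),
    c(162.798941074360, 4.45306583482e-36),
    c(0.563769508809, 7.54360616262e-01),
    c(15.486659391946, 4.33625328125e-04),
    c(26.988759663231, 1.37868579967e-06),
    c(3.248734379844, 1.97036322332e-01),
    c(2.991374309299, 2.24094564190e-01),
    c(0.801221360190, 6.69910819892e-01),
    c(1.953726089781, 3.76490281475e-01),
    c(84.601236886280, 4.25671750166e-19)
  )
  set.seed(424242)
  for (i in 1:10) {
    n <- sample(c(10, 20, 50, 100, 200), 1)
    kind <- i %% 3
    x <- if (kind == 0) rnorm(n) else if (kind == 1) rexp(n) else runif(n)^2
    d <- dagostino_pearson(x)
    expect_equal(d$statistic, expected[[i]][1], tolerance = 1e-8)
    expect_equal(d$p.value, expected[[i]][2], tolerance = 1e-8)
  }
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("the omnibus test is calibrated and has power", {
  set.seed(961)
  normal_ok <- vapply(1:20, function(i) {
    dagostino_pearson(rnorm(500))$p.value > 0.05
  }, logical(1))
  expect_gte(sum(normal_ok), 18)
  exp_reject <- vapply(1:20, function(i) {
    dagostino_pearson(rexp(100))$p.value < 0.05
  }, logical(1))
  expect_gte(sum(exp_reject), 18)
})

test_that("compare_groups gates on normality and handles ties", {
  # identical samples: Mann-Whitney branch (ties block the t-gate), p = 1
  g <- c(1, 2, 3, 4, 5)
  cmp <- compare_groups(g, g)
  expect_equal(cmp$test, "mann_whitney")
  expect_equal(cmp$p.value, 1)

  # two clean normal samples, means 0 vs 2: t branch, tiny p
  set.seed(97)
  cmp2 <- compare_groups(rnorm(20), rnorm(20, mean = 2))
  expect_equal(cmp2$test, "t")
  expect_lt(cmp2$p.value, 0.001)

  # a clearly non-normal group forces the Mann-Whitney branch
  set.seed(98)
  cmp3 <- compare_groups(rexp(30)^3, rnorm(30))
  expect_equal(cmp3$test, "mann_whitney")

  expect_error(compare_groups(1:2, 1:10), "fewer than 3")
})

test_that("salvaged vs intact comparison is significant under rho = 3", {
  sig <- vapply(1:6, function(i) {
    cfg <- small_config(980 + i, n_genes = 16, length_nt = 1200,
                        interval = c(4, 11), p_loss = 0, p_salvage = 1,
                        rho = 3, coverage = 1)
    rep <- run_pipeline(run_config(sim = cfg, stages = "rates",
                                   use_truth_fates = TRUE))
    !is.null(rep$comparison) && rep$comparison$p.value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})
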