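# Synteny blocks, inversions, breakpoints and gene fates.

ref_order <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(gene = sprintf("g%02d", 1:n),
                 strand = sample(c("+", "-"), n, TRUE))
}

# lay a signed order onto a genome table, one scaffold
order_to_genome <- function(order, scaffold = "s1") {
  n <- nrow(order)
  tibble::tibble(gene = order$gene, scaffold = scaffold,
                 start = seq(1, by = 1000, length.out = n),
                 end = seq(500, by = 1000, length.out = n),
                 strand = order$strand)
}

test_that("extract_locus windows and truncation flags behave", {
  ord <- ref_order(9, seed = 71)
  genome <- order_to_genome(ord)
  # minimal window
  w <- extract_locus(genome, ord$gene[5], 1, 1)
  expect_equal(w$gene, ord$gene[4:6])
  # boundary truncation
  w2 <- extract_locus(genome, ord$gene[2], 25, 2)
  expect_equal(w2$gene, ord$gene[1:4])
  expect_equal(attr(w2, "truncated_up"), 24)
  expect_equal(attr(w2, "truncated_down"), 0)
  expect_error(extract_locus(genome, "nope", 1, 1), "anchor")
  # 25-up/25-down on a 51-gene scaffold returns all 51 genes
  big <- ref_order(51)
  gbig <- order_to_genome(big)
  expect_equal(nrow(extract_locus(gbig, big$gene[26])), 51)
})

test_that("map_to_reference places genes by id and flags absences", {
  ord <- ref_order(8, seed = 72)
  genome <- order_to_genome(ord)
  pl <- map_to_reference(ord, genome)
  expect_true(all(pl$present))
  expect_equal(pl$t_index, 1:8)
  expect_true(all(pl$relative_sign == "+"))
  # three genes missing
  pl2 <- map_to_reference(ord, genome[-c(2, 5, 7), ])
  expect_equal(pl2$gene[!pl2$present], ord$gene[c(2, 5, 7)])
  # duplicate annotation rejected
  expect_error(map_to_reference(ord, rbind(genome, genome[1, ])),
               "duplicate")
})

test_that("find_blocks decomposes identity and single inversions", {
  ord <- ref_order(10, seed = 73)
  # identical genome: one block, orientation same
  bl <- find_blocks(ord, map_to_reference(ord, order_to_genome(ord)))
  expect_equal(nrow(bl), 1)
  expect_equal(bl$orientation, "same")
  expect_equal(bl$size, 10)
  expect_equal(count_breakpoints(bl, map_to_reference(ord, order_to_genome(ord))), 0L)

  # one inversion: prefix same, inverted middle, suffix same
  inv <- apply_inversion(ord, 4, 7)
  pl <- map_to_reference(ord, order_to_genome(inv))
  bl2 <- find_blocks(ord, pl)
  expect_equal(nrow(bl2), 3)
  expect_equal(bl2$orientation, c("same", "inverted", "same"))
  expect_equal(detect_inversions(bl2)$ref_start, 4)
  expect_equal(detect_inversions(bl2)$ref_end, 7)

  # double application restores the original: no inversions
  bl3 <- find_blocks(ord, map_to_reference(
    ord, order_to_genome(apply_inversion(inv, 4, 7))))
  expect_equal(nrow(detect_inversions(bl3)), 0)
})

test_that("block decomposition partitions present genes (random permutations)", {
  set.seed(74)
  for (i in 1:25) {
    ord <- ref_order(10)
    perm <- ord[sample(10), ]
    perm$strand <- sample(c("+", "-"), 10, TRUE)
    pl <- map_to_reference(ord, order_to_genome(perm))
    bl <- find_blocks(ord, pl)
    expect_equal(sum(bl$size), 10)
    # brute-force maximal-run oracle on the same placements
    runs <- 0L
    pp <- dplyr::arrange(dplyr::filter(pl, present), ref_index)
    prev_ok <- FALSE
    for (k in seq_len(nrow(pp))) {
      if (k == 1) { runs <- 1L; next }
      same_sc <- pp$scaffold[k] == pp$scaffold[k - 1]
      d <- pp$t_index[k] - pp$t_index[k - 1]
      adj <- same_sc && pp$ref_index[k] == pp$ref_index[k - 1] + 1 &&
        ((d == 1 && pp$relative_sign[k] == "+" &&
            pp$relative_sign[k - 1] == "+") ||
           (d == -1 && pp$relative_sign[k] == "-" &&
              pp$relative_sign[k - 1] == "-"))
      if (!adj) runs <- runs + 1L
    }
    expect_equal(nrow(bl), runs)
  }
})

test_that("a single injected inversion is recovered exactly (200 cases)", {
  set.seed(75)
  hits <- vapply(1:200, function(i) {
    n <- sample(6:20, 1)
    ord <- ref_order(n)
    ij <- sort(sample(n, 2, replace = TRUE))
    target <- apply_inversion(ord, ij[1], ij[2])
    inv <- detect_inversions(find_blocks(ord, map_to_reference(
      ord, order_to_genome(target))))
    nrow(inv) == 1 && inv$ref_start == ij[1] && inv$ref_end == ij[2]
  }, logical(1))
  expect_true(all(hits))
})

test_that("classify_fates reproduces the transcribed chicken worked example", {
  report <- fixture_disruption_report("chicken")
  tab <- table(report$fates$fate)
  expect_equal(unname(tab[["retained_in_locus"]]), 14)
  expect_equal(unname(tab[["salvaged"]]), 5)
  expect_equal(unname(tab[["lost"]]), 12)
  expect_equal(report$disrupted_segments$n_genes[1], 17)
  ref <- load_fixture("locus_reference")
  seg <- report$disrupted_segments[1, ]
  expect_equal(ref$gene[seg$ref_start], "CCDC68")
  expect_equal(ref$gene[seg$ref_end], "MYO5B")
  # intact species: everything retained, no disrupted segment
  refg <- load_fixture("genome_reference")
  pres <- tibble::tibble(gene = ref$gene, status = "detected")
  pl <- map_to_reference(ref, refg)
  intact <- classify_fates(ref, pl, pres, find_blocks(ref, pl), "reference")
  expect_true(all(intact$fates$fate == "retained_in_locus"))
  expect_equal(nrow(intact$disrupted_segments), 0)
})

test_that("classify_fates is invariant to scaffold relabelling", {
  ref <- load_fixture("locus_reference")
  genome <- load_fixture("genome_chicken")
  pres <- dplyr::filter(load_fixture("fig3_presence"), species == "chicken")
  relabel <- genome
  relabel$scaffold <- paste0("X_", relabel$scaffold)
  f1 <- classify_fates(ref, map_to_reference(ref, genome), pres,
                       find_blocks(ref, map_to_reference(ref, genome)))
  f2 <- classify_fates(ref, map_to_reference(ref, relabel), pres,
                       find_blocks(ref, map_to_reference(ref, relabel)))
  expect_equal(f1$fates, f2$fates)
  expect_equal(f1$disrupted_segments, f2$disrupted_segments)
})

test_that("fates recovered from simulations match the truth labels", {
  oks <- vapply(1:10, function(i) {
    cfg <- small_config(700 + i, length_nt = 600, coverage = 3)
    rep <- run_pipeline(run_config(sim = cfg,
                                   stages = c("detect", "synteny")))
    rep$recovery$fate_accuracy == 1.0
  }, logical(1))
  expect_true(all(oks))
})
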