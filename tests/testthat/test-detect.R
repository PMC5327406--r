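# The tiered detection cascade.

make_small_world <- function(seed = 61) {
  cfg <- small_config(seed)
  sim <- simulate_locus(cfg)
  paralog_id <- paste0(cfg$target_gene, "_paralog")
  list(cfg = cfg, sim = sim, paralog_id = paralog_id)
}

species_tables <- function(sim, sp) {
  genome <- dplyr::filter(sim$genomes, species == sp)
  sq <- dplyr::filter(sim$sequences, species == sp)
  list(genome = genome,
       assembly = setNames(sq$seq, sq$gene),
       reads = dplyr::filter(sim$reads, species == sp)[, c("read_id", "seq")])
}

test_that("annotated genes are detected at the annotation tier", {
  w <- make_small_world()
  tabs <- species_tables(w$sim, "duck")
  baits <- locusdrift:::make_baits(w$sim$sequences, "G01", w$paralog_id,
                                   "crow")
  rec <- call_gene_status("G01", "duck", tabs$genome, tabs$assembly,
                          tabs$reads, baits)
  expect_equal(rec$status, "detected")
  expect_equal(rec$tier, "annotation")
  expect_gt(rec$identity, 75)
})

test_that("a simulator-deleted gene fails all three tiers", {
  w <- make_small_world()
  lost <- w$sim$truth$events[[1]]$lost
  expect_gt(length(lost), 0)
  g <- lost[1]
  tabs <- species_tables(w$sim, "chicken")
  baits <- locusdrift:::make_baits(w$sim$sequences, g, w$paralog_id, "crow")
  rec <- call_gene_status(g, "chicken", tabs$genome, tabs$assembly,
                          tabs$reads, baits)
  expect_equal(rec$status, "not_detected")
  expect_true(is.na(rec$tier))
  expect_equal(attr(rec, "tiers_tried"),
               c("annotation", "assembly", "reads"))
})

test_that("an unannotated gene still present in the assembly is found at tier 2", {
  w <- make_small_world()
  tabs <- species_tables(w$sim, "duck")
  baits <- locusdrift:::make_baits(w$sim$sequences, "G02", w$paralog_id,
                                   "crow")
  # hide the annotation and the record id, keep the sequence
  genome2 <- dplyr::filter(tabs$genome, gene != "G02")
  assembly2 <- tabs$assembly
  names(assembly2)[names(assembly2) == "G02"] <- "unplaced_contig_7"
  rec <- call_gene_status("G02", "duck", genome2, assembly2, NULL, baits)
  expect_equal(rec$status, "detected")
  expect_equal(rec$tier, "assembly")
  expect_equal(rec$evidence, "unplaced_contig_7")
})

test_that("the cascade errors without baits", {
  w <- make_small_world()
  tabs <- species_tables(w$sim, "duck")
  expect_error(
    call_gene_status("G01", "duck", tabs$genome, tabs$assembly, NULL,
                     list(ortholog_nt = "ACGT")),
    "baits"
  )
})

test_that("raising the bit-score floor never turns not_detected into detected", {
  w <- make_small_world(62)
  tabs <- species_tables(w$sim, "chicken")
  genes <- c(w$sim$truth$events[[1]]$lost[1], "G01")
  genes <- genes[!is.na(genes)]
  floors <- c(10, 25, 40, 80)
  for (g in genes) {
    baits <- locusdrift:::make_baits(w$sim$sequences, g, w$paralog_id,
                                     "crow")
    status <- vapply(floors, function(f) {
      th <- pipeline_thresholds(relaxed_min_bitscore = f)
      call_gene_status(g, "chicken", tabs$genome, tabs$assembly,
                       tabs$reads, baits, th)$status
    }, character(1))
    detected <- status == "detected"
    # once lost at some floor, never regained at a higher floor
    expect_true(all(diff(detected) <= 0),
                label = paste("monotone for", g))
  }
})

test_that("the full presence matrix matches the simulation truth exactly", {
  cfg <- small_config(63)
  rep <- run_pipeline(run_config(sim = cfg, stages = c("detect", "synteny")))
  truth <- locusdrift:::truth_fates(rep$sim)
  joined <- dplyr::left_join(rep$presence, truth, by = c("gene", "species"))
  expect_true(all((joined$status == "detected") ==
                    (joined$fate != "lost")))
  # fate recovery, while we are here
  expect_equal(rep$recovery$fate_accuracy, 1.0)
})
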