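# The locus simulator: event containment, truth consistency, byte-level
# determinism, and the truth JSON round trip.

test_that("no-event configurations copy the root locus to every tip", {
  cfg <- small_config(1, branches = NULL, interval = NULL)
  sim <- simulate_locus(cfg)
  expect_length(sim$truth$events, 0)
  for (sp in setdiff(sim$tree$tip.label, cfg$outgroup)) {
    g <- dplyr::filter(sim$genomes, species == sp, gene != "G06_paralog") |>
      dplyr::arrange(start)
    expect_equal(g$gene, cfg$locus$gene)
    expect_equal(g$strand, cfg$locus$strand)
    expect_true(all(g$scaffold == "locus_scaffold"))
  }
})

test_that("a forced disruption affects exactly the tips below its branch", {
  cfg <- small_config(2)
  sim <- simulate_locus(cfg)
  ev <- sim$truth$events[[1]]
  expect_equal(ev$branch, "galliformes")
  below <- c("chicken", "quail")
  for (sp in setdiff(sim$tree$tip.label, cfg$outgroup)) {
    genes <- dplyr::filter(sim$genomes, species == sp)$gene
    if (sp %in% below) {
      expect_true(all(!ev$lost %in% genes))
      salv_scaf <- dplyr::filter(sim$genomes, species == sp,
                                 gene %in% ev$salvaged)$scaffold
      expect_true(all(grepl("^salvage_scaffold", salv_scaf)))
    } else {
      expect_true(all(cfg$locus$gene %in% genes))
    }
  }
})

test_that("truth log is internally consistent with the emitted outputs", {
  cfg <- small_config(3, p_loss = 0.6)
  sim <- simulate_locus(cfg)
  ev <- sim$truth$events[[1]]
  expect_length(intersect(ev$lost, ev$salvaged), 0)
  interval_genes <- cfg$locus$gene[seq(ev$interval[1], ev$interval[2])]
  expect_true(all(c(ev$lost, ev$salvaged) %in% interval_genes))
  # every gene absent from a tip is in the lost set of an ancestral event;
  # every singleton-scaffold locus gene is in a salvaged set
  for (sp in c("chicken", "quail")) {
    g <- dplyr::filter(sim$genomes, species == sp)
    absent <- setdiff(cfg$locus$gene, g$gene)
    expect_true(all(absent %in% sim$truth$lost))
    on_salvage <- g$gene[grepl("^salvage_scaffold", g$scaffold)]
    expect_true(all(on_salvage %in% sim$truth$salvaged))
  }
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- small_config(4, n_genes = 8, length_nt = 300, coverage = 2,
                      interval = c(4, 5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim(simulate_locus(cfg), d1)
  write_sim(simulate_locus(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("the truth log round-trips losslessly through JSON", {
  cfg <- small_config(5)
  sim <- simulate_locus(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(sim$truth, f)
  back <- read_sim_truth(f)
  expect_equal(back$events, sim$truth$events)
  expect_equal(back$lost, sim$truth$lost)
  expect_equal(back$salvaged, sim$truth$salvaged)
  expect_equal(back$seed, sim$truth$seed)
  expect_equal(as.data.frame(back$rates), as.data.frame(sim$truth$rates))
})

test_that("unreachable configurations are rejected before any output", {
  expect_error(sim_config(inversion_interval = c(2, 30)), "interval|flank")
  expect_error(sim_config(inversion_interval = c(2, 18)), "flank")
  expect_error(sim_config(inversion_interval = c(0, 3)), "interval|flank")
  expect_error(sim_config(rho = 0.5), "rho")
  expect_error(sim_config(p_loss = 1.5), "p_loss")
  expect_error(sim_config(locus = default_locus(length_nt = 1000)),
               "multiple")
})
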