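# Paralog filtering and orthology verification.

test_that("paralog_filter applies the joint length/identity rule", {
  set.seed(51)
  ref <- random_dna_str(600)
  th <- pipeline_thresholds()

  # perfect 120-nt substring of the paralog: discarded
  hit <- substr(ref, 101, 220)
  expect_length(paralog_filter(hit, ref, th), 0)

  # 39-nt perfect match: retained (length gate fails); embed in random flanks
  short <- paste0(random_dna_str(15), substr(ref, 200, 238))
  # guard: its best local alignment really is the 39-nt block
  aln <- local_align(short, ref, nt_score_matrix(),
                     th$gap_open_nt, th$gap_extend_nt)
  if (aln$length <= 40) expect_length(paralog_filter(short, ref, th), 1)

  # unrelated contig: retained
  expect_length(paralog_filter(random_dna_str(200), ref, th), 1)
})

test_that("paralog_filter is idempotent and keeps input order", {
  set.seed(52)
  ref <- random_dna_str(500)
  contigs <- tibble::tibble(
    contig_id = c("c1", "c2", "c3"),
    seq = c(random_dna_str(150), substr(ref, 50, 260), random_dna_str(90))
  )
  once <- paralog_filter(contigs, ref)
  twice <- paralog_filter(once, ref)
  expect_equal(once, twice)
  expect_equal(once$contig_id, c("c1", "c3"))
})

test_that("paralog contigs are discarded and ortholog contigs retained on simulated reads", {
  th <- pipeline_thresholds()
  set.seed(50)
  hits <- replicate(50, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    paralog_ref <- random_dna_str(600)
    paralog_copy <- evolve_sequence(paralog_ref, 0.02)   # close to the bait
    ortholog <- evolve_sequence(paralog_ref, 0.4)        # true, diverged gene
    par_reads <- fragment_reads(paralog_copy, 8, 100, 0, "par")
    ort_reads <- fragment_reads(ortholog, 8, 100, 0, "ort")
    contigs <- dplyr::bind_rows(
      greedy_assemble(par_reads[, c("read_id", "seq")], 20),
      greedy_assemble(ort_reads[, c("read_id", "seq")], 20)
    )
    kept <- paralog_filter(contigs, paralog_ref, th)
    par_gone <- !any(grepl("^par", kept$contig_id))
    ort_kept <- any(grepl("^ort", kept$contig_id))
    par_gone && ort_kept
  })
  expect_gte(mean(hits), 0.95)
})

test_that("verify_ortholog accepts identity, rejects short alignments", {
  set.seed(53)
  ref <- random_dna_str(900)
  panel <- tibble::tibble(
    id = "ref", family = "target",
    protein = translate_six_frames(ref)$protein[1]
  )
  v <- verify_ortholog(ref, ref, panel)
  expect_equal(v$status, "accepted")
  expect_equal(v$reason, "identity")
  expect_equal(v$identity, 100)

  # unrelated sequence: whatever route it takes, it must be rejected
  v2 <- verify_ortholog(random_dna_str(900), ref, panel)
  expect_equal(v2$status, "rejected")

  # moderate divergence below the fast-evolver bound but under the identity
  # cut: rejected as low identity
  set.seed(54)
  cand <- evolve_sequence(ref, 0.35)
  v3 <- verify_ortholog(cand, ref, panel)
  expect_equal(v3$status, "rejected")
  expect_equal(v3$reason, "low_identity")
})

test_that("fast-evolving true orthologs pass via best-hit consistency", {
  accepted <- replicate(50, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    # an ancestral CDS without internal stops in frame +1 keeps the ORF long
    n_aa <- 220
    aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    codons <- names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE %in% aa_pool]
    anc <- paste(sample(codons, n_aa, TRUE), collapse = "")
    ref <- evolve_sequence(anc, 0.05)
    paralog <- evolve_sequence(anc, 1.2)
    # "atypical" ortholog: rate multiplier 4 on a 0.15-long lineage
    cand <- evolve_sequence(anc, 4 * 0.15)
    panel <- tibble::tibble(
      id = c("sp1_t", "sp2_t", "sp1_p"),
      family = c("target", "target", "paralog"),
      protein = c(translate_six_frames(ref)$protein[1],
                  translate_six_frames(evolve_sequence(anc, 0.1))$protein[1],
                  translate_six_frames(paralog)$protein[1])
    )
    v <- verify_ortholog(cand, ref, panel)
    v$status == "accepted" && v$reason == "besthit_consistency"
  })
  expect_gte(mean(accepted), 0.90)
})

test_that("candidates whose target alignment is too short are rejected", {
  set.seed(55)
  ref <- random_dna_str(900)
  # candidate: unrelated, but its ORF carries a short exact copy from the
  # reference protein, forcing the best-hit route into the aligned-length
  # gate (alignment well under the 20-aa minimum)
  ref_prot <- translate_six_frames(ref)$protein[1]
  aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  codons <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE %in% aa_pool]
  borrowed <- gsub("[*X]", "A", substr(ref_prot, 5, 18))   # 14 aa
  back_translate <- function(p) {
    paste(vapply(strsplit(p, "")[[1]], function(a) {
      names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
    }, character(1)), collapse = "")
  }
  cand <- paste0(paste(sample(codons, 60, TRUE), collapse = ""),
                 back_translate(borrowed),
                 paste(sample(codons, 60, TRUE), collapse = ""))
  panel <- tibble::tibble(id = "ref", family = "target", protein = ref_prot)
  # lower the support floor so the candidate reaches the aligned-length gate
  th <- pipeline_thresholds(panel_min_bitscore = 25)
  v <- verify_ortholog(cand, ref, panel, th)
  expect_equal(v$status, "rejected")
  expect_equal(v$reason, "short_alignment")
  expect_lt(v$aligned_aa, 20)
  # at the default support floor the same candidate has no panel support
  v2 <- verify_ortholog(cand, ref, panel)
  expect_equal(v2$status, "rejected")
  expect_equal(v2$reason, "no_panel_support")
})
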