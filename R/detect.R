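# The tiered presence/absence decision cascade: annotation lookup (tier 1),
# translated local-alignment search of assembly sequences (tier 2), and
# read-level search with greedy assembly, paralog filtering and orthology
# verification (tier 3).

#' Thresholds of the detection cascade
#'
#' All tunables of the presence/absence pipeline in one validated object.
#' Identity-type thresholds are fractions in `[0, 1]`; lengths are in
#' residues/nt.
#'
#' @param relaxed_min_bitscore bit-score floor of the relaxed translated
#'   search (deterministic stand-in for a permissive E-value cut-off).
#' @param orf_min_aa minimum open-reading-frame length for translating
#'   candidate contigs.
#' @param read_merge_identity overlap identity required to merge reads.
#' @param read_min_overlap minimum read overlap in nt.
#' @param paralog_id,paralog_minlen_nt a contig is discarded as paralog-derived
#'   when its best local nucleotide alignment to the paralog reference is
#'   longer than `paralog_minlen_nt` AND more identical than `paralog_id`.
#' @param ortholog_min_identity global nucleotide identity (aligned columns,
#'   terminal gaps excluded) above which a candidate is accepted outright.
#' @param fast_evolver_branchlength JC69-corrected divergence above which the
#'   best-hit consistency route is allowed for candidates failing the
#'   identity rule.
#' @param min_aligned_aa minimum aligned protein length for acceptance via
#'   best-hit consistency.
#' @param besthit_panel_top_k number of top panel hits entering the majority
#'   vote.
#' @param panel_min_bitscore support floor for a panel hit to enter the
#'   best-hit vote. Stricter than the tier-2 screening floor: the vote
#'   re-creates "consistent annotation of the top database hits", and
#'   annotated database hits are solid homologies, not borderline scores;
#'   40 bits is the classic rule-of-thumb boundary for that. Random
#'   alignments across the six-frame x panel search space stay far below
#'   it.
#' @param protein_word,nt_word exact word sizes of the seed-and-extend
#'   prefilters (protein tier-2 search, nucleotide read search).
#' @param min_read_score minimum local nucleotide score for a read to count
#'   as a hit against the bait.
#' @param gap_open_aa,gap_extend_aa protein affine gap costs.
#' @param nt_match,nt_mismatch,gap_open_nt,gap_extend_nt nucleotide scoring.
#' @param karlin_lambda,karlin_K Karlin-Altschul parameters for [bit_score()].
#' @param max_salvage_block maximum number of reference-locus genes on a
#'   scaffold for its genes to count as salvaged (see [classify_fates()]).
#' @return An object of class `pipeline_thresholds`.
#' @export
pipeline_thresholds <- function(relaxed_min_bitscore = 25,
                                orf_min_aa = 50,
                                read_merge_identity = 0.97,
                                read_min_overlap = 20,
                                paralog_id = 0.95,
                                paralog_minlen_nt = 40,
                                ortholog_min_identity = 0.75,
                                fast_evolver_branchlength = 0.4,
                                min_aligned_aa = 20,
                                besthit_panel_top_k = 5,
                                panel_min_bitscore = 40,
                                protein_word = 6,
                                nt_word = 16,
                                min_read_score = 20,
                                gap_open_aa = 11, gap_extend_aa = 1,
                                nt_match = 1, nt_mismatch = -1,
                                gap_open_nt = 5, gap_extend_nt = 2,
                                karlin_lambda = 0.267, karlin_K = 0.041,
                                max_salvage_block = 2) {
  th <- as.list(environment())
  for (p in c("read_merge_identity", "paralog_id", "ortholog_min_identity")) {
    stopifnot_scalar_number(th[[p]], p, 0, 1)
  }
  for (p in c("orf_min_aa", "read_min_overlap", "paralog_minlen_nt",
              "min_aligned_aa", "besthit_panel_top_k", "protein_word",
              "nt_word", "max_salvage_block")) {
    if (th[[p]] < 1 || th[[p]] != round(th[[p]])) {
      abort(sprintf("`%s` must be a positive integer", p))
    }
  }
  structure(th, class = "pipeline_thresholds")
}

#' @export
print.pipeline_thresholds <- function(x, ...) {
  cat("<pipeline_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Discard contigs that match the paralog reference
#'
#' A contig is discarded iff its best local nucleotide alignment to the
#' paralog reference spans more than `paralog_minlen_nt` aligned columns AND
#' exceeds `paralog_id` identity (blastn-style local semantics). All other
#' contigs are retained in their input order. The filter is idempotent.
#'
#' @param contigs tibble with columns `contig_id`, `seq` (or a character
#'   vector of sequences).
#' @param paralog_reference nucleotide sequence of the paralog bait.
#' @param thresholds a [pipeline_thresholds()].
#' @return The retained contigs, same type as the input.
#' @export
paralog_filter <- function(contigs, paralog_reference,
                           thresholds = pipeline_thresholds()) {
  seqs <- if (is.data.frame(contigs)) contigs$seq else contigs
  if (length(seqs) == 0) return(contigs)
  mat <- nt_score_matrix(thresholds$nt_match, thresholds$nt_mismatch)
  keep <- vapply(seqs, function(s) {
    aln <- local_align(s, paralog_reference, mat,
                       thresholds$gap_open_nt, thresholds$gap_extend_nt)
    !(aln$length > thresholds$paralog_minlen_nt &&
        !is.na(aln$percent_identity) &&
        aln$percent_identity / 100 > thresholds$paralog_id)
  }, logical(1), USE.NAMES = FALSE)
  if (is.data.frame(contigs)) contigs[keep, ] else contigs[keep]
}

# identity / mismatch statistics of a global nt alignment, excluding terminal
# gap columns; comparable columns are those where both sequences have a base
global_identity_stats <- function(candidate, reference, thresholds) {
  if (nchar(candidate) == nchar(reference)) {
    # equal lengths: the ungapped column comparison IS the global alignment
    # of interest (indel-free setting); avoids a quadratic DP
    p <- hamming_frac(candidate, reference)
    return(list(identity = 1 - p, p_mismatch = p,
                columns = nchar(candidate)))
  }
  aln <- global_align_nt(candidate, reference,
                         thresholds$nt_match, thresholds$nt_mismatch,
                         thresholds$gap_open_nt, thresholds$gap_extend_nt)
  a <- chars(aln$a); b <- chars(aln$b)
  non_gap_a <- which(a != "-"); non_gap_b <- which(b != "-")
  lo <- max(min(non_gap_a), min(non_gap_b))
  hi <- min(max(non_gap_a), max(non_gap_b))
  if (lo > hi) {
    return(list(identity = NA_real_, p_mismatch = NA_real_, columns = 0L))
  }
  a <- a[lo:hi]; b <- b[lo:hi]
  cols <- length(a)
  match_n <- sum(a == b & a != "-")
  both <- a != "-" & b != "-"
  list(
    identity = match_n / cols,
    p_mismatch = if (sum(both) == 0) NA_real_
                 else sum(a[both] != b[both]) / sum(both),
    columns = cols
  )
}

#' Verify the orthology of a candidate sequence
#'
#' Accepts a candidate outright when its global nucleotide identity to the
#' reference ortholog (over aligned columns, terminal gaps excluded) exceeds
#' `ortholog_min_identity`. Otherwise the JC69-corrected divergence is
#' estimated; fast-evolving candidates (divergence above
#' `fast_evolver_branchlength`) are accepted only when the majority label of
#' the top-k best panel hits equals the target family and the best
#' target-family alignment covers at least `min_aligned_aa` residues.
#' Everything else is rejected with a machine-readable reason.
#'
#' @param candidate nucleotide sequence under test.
#' @param reference_ortholog nucleotide sequence of the reference ortholog.
#' @param reference_panel labelled protein panel: tibble with columns `id`,
#'   `family`, `protein`; the target family is named `target_family`.
#' @param thresholds a [pipeline_thresholds()].
#' @param target_family family label the candidate must vote for.
#' @return Object of class `ortholog_verdict`: `status` ("accepted" /
#'   "rejected"), `reason`, `identity` (percent), `divergence`
#'   (substitutions/site), `aligned_aa`, `besthit_pass`, `votes`.
#' @export
verify_ortholog <- function(candidate, reference_ortholog, reference_panel,
                            thresholds = pipeline_thresholds(),
                            target_family = "target") {
  if (nchar(candidate) == 0) abort("`candidate` must be non-empty")
  st <- global_identity_stats(candidate, reference_ortholog, thresholds)
  verdict <- function(status, reason, divergence = NA_real_,
                      aligned_aa = NA_integer_, besthit = NA, votes = NULL) {
    structure(list(status = status, reason = reason,
                   identity = 100 * st$identity,
                   divergence = divergence, aligned_aa = aligned_aa,
                   besthit_pass = besthit, votes = votes),
              class = "ortholog_verdict")
  }
  if (is.na(st$identity) || is.na(st$p_mismatch)) {
    return(verdict("rejected", "no_alignment"))
  }
  divergence <- jc69_distance(st$p_mismatch)
  if (st$identity > thresholds$ortholog_min_identity) {
    return(verdict("accepted", "identity", divergence))
  }
  if (!is.infinite(divergence) &&
      divergence <= thresholds$fast_evolver_branchlength) {
    return(verdict("rejected", "low_identity", divergence))
  }
  # fast-evolver route: best-hit consistency over the labelled panel,
  # aligning all six frame translations against every panel member
  # (blastx-style; candidate frames may be interrupted by stops)
  S <- blosum62_matrix()
  frames <- translate_six_frames(candidate)$protein
  frames <- frames[nchar(frames) > 0]
  enc_frames <- lapply(frames, encode_seq, alphabet = rownames(S),
                       what = "frame")
  votes <- purrr::pmap(reference_panel, function(id, family, protein, ...) {
    enc_p <- encode_seq(protein, rownames(S), "panel")
    per_frame <- vapply(enc_frames, function(ef) {
      .sw_align(ef, enc_p, S, thresholds$gap_open_aa,
                thresholds$gap_extend_aa, FALSE)$score
    }, numeric(1))
    tibble(id = id, family = family, score = max(per_frame),
           frame = which.max(per_frame),
           bits = bit_score(max(per_frame), thresholds$karlin_lambda,
                            thresholds$karlin_K))
  }) |> bind_rows() |>
    filter(.data$bits >= thresholds$panel_min_bitscore) |>
    arrange(dplyr::desc(.data$score), .data$id)
  if (nrow(votes) == 0) {
    return(verdict("rejected", "no_panel_support", divergence, votes = votes))
  }
  top <- head(votes, thresholds$besthit_panel_top_k)
  tab <- sort(table(top$family), decreasing = TRUE)
  majority <- names(tab)[1]
  best_target <- filter(top, .data$family == target_family)
  aligned_aa <- if (nrow(best_target) == 0) 0L else {
    # aligned length of the single best target-family hit (traceback pass)
    row <- best_target[1, ]
    enc_p <- encode_seq(
      reference_panel$protein[reference_panel$id == row$id][1],
      rownames(S), "panel")
    length(.sw_align(enc_frames[[row$frame]], enc_p, S,
                     thresholds$gap_open_aa, thresholds$gap_extend_aa,
                     TRUE)$q_aln)
  }
  if (majority != target_family) {
    return(verdict("rejected", "inconsistent_besthit", divergence,
                   aligned_aa, FALSE, votes))
  }
  if (aligned_aa < thresholds$min_aligned_aa) {
    return(verdict("rejected", "short_alignment", divergence,
                   aligned_aa, TRUE, votes))
  }
  verdict("accepted", "besthit_consistency", divergence, aligned_aa, TRUE,
          votes)
}

#' @export
print.ortholog_verdict <- function(x, ...) {
  cat(sprintf("<ortholog_verdict> %s (%s); identity %.1f%%, divergence %s\n",
              x$status, x$reason, x$identity,
              ifelse(is.na(x$divergence), "NA", sprintf("%.3f", x$divergence))))
  invisible(x)
}

# best translated local alignment of the bait protein against the six-frame
# translations of one nucleotide sequence, with an exact-word prefilter
best_translated_hit <- function(bait_aa, target_nt, thresholds,
                                bait_words = NULL) {
  frames <- translate_six_frames(target_nt)
  bait_words <- bait_words %||% kmer_set(bait_aa, thresholds$protein_word)
  S <- blosum62_matrix()
  q <- encode_seq(bait_aa, rownames(S), "bait")
  best <- NULL
  for (i in seq_len(nrow(frames))) {
    prot <- frames$protein[i]
    if (nchar(prot) < thresholds$protein_word) next
    if (!shares_kmer(bait_words, prot, thresholds$protein_word)) next
    # score-only pass: the hit's evidence is the target record itself
    sc <- .sw_align(q, encode_seq(prot, rownames(S), "frame"), S,
                    thresholds$gap_open_aa, thresholds$gap_extend_aa,
                    FALSE)$score
    if (is.null(best) || sc > best$score) {
      best <- list(frame = frames$frame[i], score = sc)
    }
  }
  best
}

#' Call the presence/absence status of one gene in one species
#'
#' Runs the three-tier cascade: (1) name lookup in the gene-order table,
#' (2) translated local-alignment search of the assembly sequences at the
#' relaxed bit-score floor, (3) read-level search, greedy assembly, paralog
#' filtering. Evidence from every tier must pass [verify_ortholog()]; the
#' recorded tier is the first that succeeded and the status is
#' `not_detected` only after all available tiers failed.
#'
#' @param gene,species ids for the record.
#' @param genome the species' gene-order tibble (columns `gene`, `scaffold`,
#'   `start`, `end`, `strand`).
#' @param assembly_seqs named character vector of the species' assembly
#'   sequences (names are gene/record ids).
#' @param reads tibble with columns `read_id`, `seq`, or `NULL` when no reads
#'   are available.
#' @param baits list with elements `ortholog_nt`, `ortholog_aa` (optional;
#'   translated from frame +1 when missing), `paralog_nt`, and `panel` (a
#'   labelled protein tibble as in [verify_ortholog()]).
#' @param thresholds a [pipeline_thresholds()].
#' @return One-row tibble of class `detection_record`: `gene`, `species`,
#'   `tier`, `status`, `evidence`, `identity`, `divergence`, `aligned_aa`,
#'   plus an attribute `tiers_tried`.
#' @export
call_gene_status <- function(gene, species, genome, assembly_seqs,
                             reads = NULL, baits,
                             thresholds = pipeline_thresholds()) {
  if (is.null(baits$ortholog_nt) || is.null(baits$paralog_nt) ||
      is.null(baits$panel)) {
    abort("`baits` must provide ortholog_nt, paralog_nt and panel")
  }
  bait_nt <- baits$ortholog_nt
  bait_aa <- baits$ortholog_aa %||% translate_six_frames(bait_nt)$protein[1]
  tried <- character(0)
  record <- function(tier, status, evidence, verdict = NULL) {
    out <- tibble(
      gene = gene, species = species,
      tier = tier, status = status, evidence = evidence,
      identity = verdict$identity %||% NA_real_,
      divergence = verdict$divergence %||% NA_real_,
      aligned_aa = verdict$aligned_aa %||% NA_integer_
    )
    attr(out, "tiers_tried") <- tried
    class(out) <- c("detection_record", class(out))
    out
  }

  # tier 1: annotation lookup -------------------------------------------
  tried <- c(tried, "annotation")
  if (gene %in% genome$gene) {
    seq1 <- assembly_seqs[[gene]]
    if (is.null(seq1)) {
      # annotated but no sequence available: accept the annotation
      return(record("annotation", "detected", gene))
    }
    v <- verify_ortholog(seq1, bait_nt, baits$panel, thresholds)
    if (v$status == "accepted") return(record("annotation", "detected",
                                              gene, v))
  }

  # tier 2: translated search of the assembly ---------------------------
  tried <- c(tried, "assembly")
  bait_words <- kmer_set(bait_aa, thresholds$protein_word)
  best <- NULL
  for (id in names(assembly_seqs)) {
    hit <- best_translated_hit(bait_aa, assembly_seqs[[id]], thresholds,
                               bait_words)
    if (!is.null(hit) &&
        (is.null(best) || hit$score > best$hit$score)) {
      best <- list(id = id, hit = hit)
    }
  }
  if (!is.null(best)) {
    bits <- bit_score(best$hit$score, thresholds$karlin_lambda,
                      thresholds$karlin_K)
    if (bits >= thresholds$relaxed_min_bitscore) {
      v <- verify_ortholog(assembly_seqs[[best$id]], bait_nt, baits$panel,
                           thresholds)
      if (v$status == "accepted") {
        return(record("assembly", "detected", best$id, v))
      }
    }
  }

  # tier 3: read search + assembly + paralog filter ----------------------
  if (!is.null(reads) && nrow(reads) > 0) {
    tried <- c(tried, "reads")
    bait_nt_words <- kmer_set(bait_nt, thresholds$nt_word)
    seeded <- which_share_kmer(bait_nt_words, reads$seq, thresholds$nt_word)
    hits <- reads[seeded, , drop = FALSE]
    if (nrow(hits) > 0) {
      mat <- nt_score_matrix(thresholds$nt_match, thresholds$nt_mismatch)
      scores <- vapply(hits$seq, function(s) {
        .sw_align(encode_dna(s, "read"), encode_dna(bait_nt, "bait"),
                  mat[1:4, 1:4], thresholds$gap_open_nt,
                  thresholds$gap_extend_nt, FALSE)$score
      }, numeric(1), USE.NAMES = FALSE)
      hits <- hits[scores >= thresholds$min_read_score, , drop = FALSE]
    }
    if (nrow(hits) > 0) {
      contigs <- greedy_assemble(hits[, c("read_id", "seq")],
                                 thresholds$read_min_overlap,
                                 thresholds$read_merge_identity)
      contigs <- paralog_filter(contigs, baits$paralog_nt, thresholds)
      if (nrow(contigs) > 0) {
        contigs <- contigs[order(-nchar(contigs$seq), contigs$contig_id), ]
        for (ci in seq_len(nrow(contigs))) {
          v <- verify_ortholog(contigs$seq[ci], bait_nt, baits$panel,
                               thresholds)
          if (v$status == "accepted") {
            return(record("reads", "detected", contigs$contig_id[ci], v))
          }
        }
      }
    }
  }
  record(NA_character_, "not_detected", NA_character_)
}

#' Presence/absence matrix from detection records
#'
#' @param records tibble of detection records (rows from
#'   [call_gene_status()] or a fixture detection table with columns `gene`,
#'   `species`, `status`).
#' @param gene_order optional character vector fixing the row order.
#' @return A genes x species tibble of 0/1 calls, class `presence_matrix`.
#' @export
presence_matrix <- function(records, gene_order = NULL) {
  wide <- records |>
    mutate(present = as.integer(.data$status == "detected")) |>
    select("gene", "species", "present") |>
    tidyr::pivot_wider(names_from = "species", values_from = "present",
                       values_fill = 0L)
  if (!is.null(gene_order)) {
    wide <- wide[match(gene_order, wide$gene), ]
  }
  class(wide) <- c("presence_matrix", class(wide))
  wide
}

#' Write detection records / a presence matrix as TSV
#'
#' @param records tibble of detection records.
#' @param pm a [presence_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detection_records <- function(records, path) {
  readr::write_tsv(as_tibble(records), path)
  invisible(path)
}

#' @rdname write_detection_records
#' @export
write_presence_matrix <- function(pm, path) {
  readr::write_tsv(as_tibble(pm), path)
  invisible(path)
}

#' Genes undetected in every listed species
#'
#' @param pm a [presence_matrix()].
#' @param species species (columns) that must all lack the gene.
#' @return Character vector of gene ids.
#' @export
undetected_in_all <- function(pm, species) {
  m <- as.matrix(pm[, species, drop = FALSE])
  pm$gene[rowSums(m) == 0]
}
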