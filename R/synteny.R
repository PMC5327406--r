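# Synteny-block and inversion analysis on signed gene orders, and per-gene
# fate classification (retained in locus / salvaged / lost).

#' Read / write a gene-order table
#'
#' Gene-order tables have columns `gene`, `scaffold`, `start`, `end`,
#' `strand`, with 1-based inclusive coordinates and unique gene ids.
#'
#' @param path TSV file path.
#' @return A validated tibble (reader) or `path` invisibly (writer).
#' @export
read_genome_table <- function(path) {
  gt <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          gene = "c", scaffold = "c", start = "i", end = "i",
                          strand = "c"
                        ))
  validate_genome_table(gt)
}

#' @rdname read_genome_table
#' @param genome gene-order tibble.
#' @export
write_genome_table <- function(genome, path) {
  readr::write_tsv(validate_genome_table(genome), path)
  invisible(path)
}

validate_genome_table <- function(genome) {
  genome <- as_tibble(genome)
  needed <- c("gene", "scaffold", "start", "end", "strand")
  if (!all(needed %in% names(genome))) {
    abort(paste("gene-order table needs columns",
                paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(genome$gene)) {
    dup <- genome$gene[duplicated(genome$gene)][1]
    abort(sprintf("duplicate annotation for gene '%s'", dup))
  }
  if (any(genome$start > genome$end)) abort("start must be <= end")
  if (!all(genome$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  genome
}

#' Extract a signed gene window around an anchor gene
#'
#' Returns the `n_up` genes preceding and `n_down` genes following the anchor
#' on its scaffold, in coordinate order, with strands. The window is silently
#' truncated at scaffold ends; the truncation is recorded in the
#' `truncated_up` / `truncated_down` attributes.
#'
#' @param genome gene-order tibble.
#' @param anchor gene id present in `genome`.
#' @param n_up,n_down window half-widths in genes.
#' @return Tibble with columns `gene`, `strand` (signed order), attributes
#'   `truncated_up`, `truncated_down` (counts of missing window genes).
#' @export
extract_locus <- function(genome, anchor, n_up = 25, n_down = 25) {
  genome <- validate_genome_table(genome)
  if (!anchor %in% genome$gene) {
    abort(sprintf("anchor gene '%s' absent from the gene-order table", anchor))
  }
  sc <- genome$scaffold[genome$gene == anchor]
  on_sc <- genome |> filter(.data$scaffold == sc) |> arrange(.data$start)
  k <- which(on_sc$gene == anchor)
  lo <- max(1, k - n_up); hi <- min(nrow(on_sc), k + n_down)
  out <- on_sc[lo:hi, c("gene", "strand")]
  attr(out, "truncated_up") <- n_up - (k - lo)
  attr(out, "truncated_down") <- n_down - (hi - k)
  out
}

#' Map reference-locus genes onto a target genome
#'
#' Each reference gene is looked up by id in the target gene-order table;
#' mapped genes get their target scaffold, within-scaffold index (rank among
#' mapped reference genes only, so intervening non-reference genes are
#' ignored) and relative sign.
#'
#' @param reference_order signed gene order (tibble `gene`, `strand`).
#' @param target target species gene-order tibble.
#' @return Tibble with one row per reference gene: `gene`, `ref_index`,
#'   `ref_strand`, `present`, `scaffold`, `t_index`, `t_strand`,
#'   `relative_sign` (`+` when target and reference strands agree).
#' @export
map_to_reference <- function(reference_order, target) {
  reference_order <- as_tibble(reference_order)
  if (anyDuplicated(reference_order$gene)) {
    abort("reference gene ids must be unique")
  }
  target <- validate_genome_table(target)
  hits <- target |>
    filter(.data$gene %in% reference_order$gene) |>
    group_by(.data$scaffold) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(t_index = row_number()) |>
    ungroup()
  ref <- reference_order |>
    mutate(ref_index = row_number()) |>
    rename(ref_strand = "strand")
  out <- left_join(ref, hits[, c("gene", "scaffold", "t_index", "strand")],
                   by = "gene") |>
    rename(t_strand = "strand") |>
    mutate(present = !is.na(.data$scaffold),
           relative_sign = ifelse(.data$present,
                                  ifelse(.data$t_strand == .data$ref_strand,
                                         "+", "-"),
                                  NA_character_))
  out[, c("gene", "ref_index", "ref_strand", "present", "scaffold",
          "t_index", "t_strand", "relative_sign")]
}

#' Decompose placements into synteny blocks
#'
#' A block is a maximal run of consecutive *present* reference genes that are
#' adjacent in the target (index difference +1 for `same` orientation, -1 for
#' `inverted`) on one scaffold with a consistent relative sign. Every present
#' gene belongs to exactly one block; single genes form size-1 blocks whose
#' orientation follows their relative sign.
#'
#' @param reference_order signed reference gene order.
#' @param placements output of [map_to_reference()].
#' @return Tibble with columns `block_id`, `ref_start`, `ref_end`, `size`,
#'   `scaffold`, `orientation` (`same`/`inverted`).
#' @export
find_blocks <- function(reference_order, placements) {
  pl <- placements |> filter(.data$present) |> arrange(.data$ref_index)
  if (nrow(pl) == 0) {
    return(tibble(block_id = integer(0), ref_start = integer(0),
                  ref_end = integer(0), size = integer(0),
                  scaffold = character(0), orientation = character(0)))
  }
  n <- nrow(pl)
  # does the pair (k, k+1) of present genes extend a block, and in which
  # orientation?
  joins <- function(k) {
    if (pl$ref_index[k + 1] != pl$ref_index[k] + 1) return(NA_character_)
    if (pl$scaffold[k + 1] != pl$scaffold[k]) return(NA_character_)
    d <- pl$t_index[k + 1] - pl$t_index[k]
    if (d == 1 && pl$relative_sign[k] == "+" &&
        pl$relative_sign[k + 1] == "+") return("same")
    if (d == -1 && pl$relative_sign[k] == "-" &&
        pl$relative_sign[k + 1] == "-") return("inverted")
    NA_character_
  }
  block_id <- integer(n); orient <- character(n)
  bid <- 1L; block_id[1] <- 1L
  run_orient <- NA_character_
  for (k in seq_len(n - 1)) {
    j <- joins(k)
    extend <- !is.na(j) && (is.na(run_orient) || j == run_orient)
    if (extend) {
      run_orient <- j
      block_id[k + 1] <- bid
    } else {
      orient[bid] <- run_orient %||% NA_character_
      bid <- bid + 1L
      block_id[k + 1] <- bid
      run_orient <- NA_character_
    }
  }
  orient[bid] <- run_orient
  pl$block_id <- block_id
  blocks <- pl |>
    group_by(.data$block_id) |>
    summarise(ref_start = min(.data$ref_index),
              ref_end = max(.data$ref_index),
              size = dplyr::n(),
              scaffold = .data$scaffold[1],
              sign_first = .data$relative_sign[1],
              .groups = "drop")
  blocks$orientation <- ifelse(
    blocks$size > 1,
    orient[blocks$block_id],
    ifelse(blocks$sign_first == "+", "same", "inverted")
  )
  blocks[, c("block_id", "ref_start", "ref_end", "size", "scaffold",
             "orientation")]
}

#' Count synteny breakpoints
#'
#' The number of reference adjacencies (both genes present) that are not
#' realised as a consistent adjacency in the target. Zero iff the target
#' equals the reference up to a global reversal.
#'
#' @param blocks output of [find_blocks()].
#' @param placements output of [map_to_reference()].
#' @return Integer breakpoint count.
#' @export
count_breakpoints <- function(blocks, placements) {
  pl <- placements |> filter(.data$present) |> arrange(.data$ref_index)
  if (nrow(pl) < 2) return(0L)
  adjacent_pairs <- sum(diff(pl$ref_index) == 1)
  realised <- sum(blocks$size - 1L)
  as.integer(adjacent_pairs - realised)
}

#' Inversion intervals among synteny blocks
#'
#' Reference intervals of all blocks with `inverted` orientation, sorted by
#' start.
#'
#' @param blocks output of [find_blocks()].
#' @return Tibble with columns `ref_start`, `ref_end`.
#' @export
detect_inversions <- function(blocks) {
  blocks |>
    filter(.data$orientation == "inverted") |>
    arrange(.data$ref_start) |>
    select("ref_start", "ref_end")
}

#' Classify the fate of every reference-locus gene in one species
#'
#' * `lost`: not detected at any tier of the cascade.
#' * `salvaged`: detected, but either placed on a scaffold carrying at most
#'   `max_salvage_block` reference-locus genes (the ancestral neighbourhood
#'   is gone) or detected only at a sequence tier with no placement.
#' * `retained_in_locus`: everything else (placed among > `max_salvage_block`
#'   reference genes).
#'
#' The disrupted segment is every maximal run of consecutive reference genes
#' none of which is `retained_in_locus`; when several maximal runs exist all
#' are reported, longest first.
#'
#' @param reference_order signed reference gene order.
#' @param placements output of [map_to_reference()] for the species.
#' @param presence detection tibble for the species: columns `gene`,
#'   `status`, optionally `tier`.
#' @param blocks output of [find_blocks()].
#' @param species species id recorded in the report.
#' @param max_salvage_block scaffold-size bound of the salvage rule.
#' @return Object of class `disruption_report`: list with `species`,
#'   `fates` (tibble `gene`, `ref_index`, `fate`), `blocks`, `inversions`,
#'   `breakpoints`, `disrupted_segments` (tibble `ref_start`, `ref_end`,
#'   `n_genes`).
#' @export
classify_fates <- function(reference_order, placements, presence, blocks,
                           species = NA_character_, max_salvage_block = 2) {
  reference_order <- as_tibble(reference_order)
  missing_genes <- setdiff(reference_order$gene, presence$gene)
  if (length(missing_genes) > 0) {
    abort(sprintf("presence table lacks reference gene '%s'",
                  missing_genes[1]))
  }
  if ("species" %in% names(presence)) {
    sp <- unique(presence$species)
    if (length(sp) > 1) abort("presence table mixes species")
    if (!is.na(species) && length(sp) == 1 && !is.na(sp[1]) &&
        sp[1] != species) {
      abort(sprintf("presence is for species '%s', placements for '%s'",
                    sp[1], species))
    }
  }
  detected <- presence$gene[presence$status == "detected"]
  scaffold_load <- placements |>
    filter(.data$present) |>
    dplyr::count(.data$scaffold, name = "n_ref_genes")
  pl <- left_join(placements, scaffold_load, by = "scaffold")
  fate <- vapply(seq_len(nrow(reference_order)), function(i) {
    g <- reference_order$gene[i]
    if (!g %in% detected) return("lost")
    row <- pl[pl$gene == g, ]
    if (!row$present) return("salvaged")      # sequence-tier only
    if (row$n_ref_genes <= max_salvage_block) return("salvaged")
    "retained_in_locus"
  }, character(1))
  fates <- tibble(gene = reference_order$gene,
                  ref_index = seq_len(nrow(reference_order)),
                  fate = fate)
  not_retained <- fates$fate != "retained_in_locus"
  runs <- rle(not_retained)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- tibble(ref_start = starts[runs$values],
                 ref_end = ends[runs$values]) |>
    mutate(n_genes = .data$ref_end - .data$ref_start + 1L) |>
    arrange(dplyr::desc(.data$n_genes), .data$ref_start)
  structure(list(
    species = species,
    fates = fates,
    blocks = blocks,
    inversions = detect_inversions(blocks),
    breakpoints = count_breakpoints(blocks, placements),
    disrupted_segments = segs
  ), class = "disruption_report")
}

#' @export
print.disruption_report <- function(x, ...) {
  cat(sprintf("<disruption_report> species %s\n", x$species))
  cat(sprintf("  %d blocks, %d inversion(s), %d breakpoint(s)\n",
              nrow(x$blocks), nrow(x$inversions), x$breakpoints))
  tab <- table(x$fates$fate)
  cat("  fates:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (nrow(x$disrupted_segments) > 0) {
    s <- x$disrupted_segments[1, ]
    cat(sprintf("  largest disrupted segment: [%d, %d] (%d genes)\n",
                s$ref_start, s$ref_end, s$n_genes))
  }
  invisible(x)
}

#' Serialise a disruption report to JSON
#'
#' @param report a `disruption_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_disruption_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
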