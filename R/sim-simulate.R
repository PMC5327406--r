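#' Simulate a conserved locus evolving along a species tree
#'
#' Draws uniform root sequences for every locus gene (plus a diverged paralog
#' of the target gene), evolves them down the tree with per-branch effective
#' rates, applies disruption events (inversion, then per-gene loss or salvage
#' to an isolated scaffold) on the configured branches, and emits per-species
#' gene-order tables, gene sequences and shotgun reads together with a
#' ground-truth event log. A single RNG stream seeded from `config$seed` is
#' consumed in a fixed traversal (pre-order over branches; within a branch the
#' event decision first, then genes in locus order), so identical
#' configurations give identical outputs.
#'
#' @param config a [sim_config()].
#' @return An object of class `locus_sim`: a list with elements `genomes`
#'   (tibble: species, gene, scaffold, start, end, strand), `sequences`
#'   (tibble: species, gene, scaffold, seq), `reads` (tibble: species,
#'   gene_src, read_id, seq, qual), `tree` (the input phylogeny with labelled
#'   nodes), `truth` (class `sim_truth`) and `config`.
#' @export
simulate_locus <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  set.seed(config$seed)
  tree <- label_nodes(config$tree)
  locus <- config$locus
  n_genes <- nrow(locus)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  paralog_id <- paste0(config$target_gene, "_paralog")

  # root state (sequences kept as integer codes until the tips) -------------
  root_seqs <- lapply(seq_len(n_genes), function(i) {
    sample.int(4L, locus$length_nt[i], replace = TRUE)
  })
  names(root_seqs) <- locus$gene
  root_seqs[[paralog_id]] <- evolve_codes(
    root_seqs[[config$target_gene]], config$paralog_divergence,
    config$subst_model, config$kappa
  )
  base_rate <- setNames(c(locus$base_rate,
                          locus$base_rate[locus$gene == config$target_gene]),
                        c(locus$gene, paralog_id))
  gene_order_all <- c(locus$gene, paralog_id)

  root_state <- list(
    seqs = root_seqs,
    order = locus[, c("gene", "strand")],
    salvaged = character(0), lost = character(0),
    mult = setNames(rep(1, length(gene_order_all)), gene_order_all)
  )

  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- root_state
  events <- list()
  rate_log <- list()

  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    st <- states[[parent]]
    branch_id <- node_name(tree, child)

    # disruption decision (RNG order: event first, then sequence evolution)
    forced <- branch_id %in% (config$disruption_branches %||% character(0))
    hit <- forced || (config$p_disrupt > 0 && runif(1) < config$p_disrupt)
    if (hit) {
      ij <- config$inversion_interval %||% {
        lo <- config$flank_genes + 1L
        hi <- n_genes - config$flank_genes
        sort(sample(seq(lo, hi), 2, replace = TRUE))
      }
      ref_interval <- locus$gene[seq(ij[1], ij[2])]
      affected <- intersect(ref_interval, st$order$gene)
      lost_now <- character(0); salv_now <- character(0)
      for (g in affected) {
        if (runif(1) < config$p_loss) lost_now <- c(lost_now, g)
        else if (runif(1) < config$p_salvage) salv_now <- c(salv_now, g)
      }
      # inversion over the contiguous span of affected genes, applied before
      # losses/relocations take effect
      pos <- which(st$order$gene %in% affected)
      if (length(pos) > 0) {
        st$order <- apply_inversion(st$order, min(pos), max(pos))
      }
      st$order <- st$order[!st$order$gene %in% c(lost_now, salv_now), ]
      st$seqs[lost_now] <- NULL
      st$lost <- union(st$lost, lost_now)
      st$salvaged <- union(st$salvaged, salv_now)
      st$mult[salv_now] <- config$rho
      events[[length(events) + 1]] <- list(
        branch = branch_id, interval = as.integer(ij),
        lost = lost_now, salvaged = salv_now
      )
    }

    # evolve surviving genes in locus order, then the paralog
    for (g in gene_order_all) {
      if (is.null(st$seqs[[g]])) next
      t_eff <- elen[e] * base_rate[[g]] * st$mult[[g]]
      st$seqs[[g]] <- evolve_codes(st$seqs[[g]], t_eff,
                                   config$subst_model, config$kappa)
    }
    rate_log[[length(rate_log) + 1]] <- tibble(
      branch = branch_id,
      gene = gene_order_all,
      multiplier = unname(st$mult[gene_order_all]),
      present = gene_order_all %in% c(names(st$seqs))
    )
    states[[child]] <- st
  }

  # tip outputs --------------------------------------------------------------
  tips <- tree$tip.label
  genomes <- list(); seq_rows <- list(); read_rows <- list()
  for (sp in tips) {
    st <- states[[match(sp, tips)]]
    st$seqs <- lapply(st$seqs, decode_dna)
    gt <- build_genome_table(st, locus, paralog_id, config$two_gene_salvage)
    genomes[[sp]] <- mutate(gt, species = sp, .before = 1)
    sq <- tibble(species = sp, gene = gt$gene, scaffold = gt$scaffold,
                 seq = map_chr(gt$gene, ~ st$seqs[[.x]]))
    seq_rows[[sp]] <- sq
    for (g in sq$gene) {
      rd <- fragment_reads(st$seqs[[g]], config$coverage, config$read_len,
                           config$err_rate,
                           id_prefix = paste0(sp, "_", g))
      read_rows[[paste(sp, g)]] <- tibble(species = sp, gene_src = g,
                                          read_id = rd$read_id, seq = rd$seq,
                                          qual = rd$qual)
    }
  }

  truth <- structure(list(
    events = events,
    rates = bind_rows(rate_log),
    lost = sort(unique(as.character(unlist(lapply(events, `[[`, "lost"))))),
    salvaged = sort(unique(as.character(unlist(lapply(events, `[[`,
                                                      "salvaged"))))),
    seed = config$seed
  ), class = "sim_truth")
  validate_sim_truth(truth, locus)

  structure(list(
    genomes = bind_rows(genomes),
    sequences = bind_rows(seq_rows),
    reads = bind_rows(read_rows),
    tree = tree, truth = truth, config = config
  ), class = "locus_sim")
}

# genome table for one tip: the locus scaffold in current order, salvaged
# genes on isolated scaffolds (one, or two when two_gene_salvage), and the
# paralog on its own scaffold
build_genome_table <- function(st, locus, paralog_id, two_gene_salvage) {
  gap <- 200L
  lens <- setNames(locus$length_nt, locus$gene)
  rows <- list()
  pos <- 1L
  for (k in seq_len(nrow(st$order))) {
    g <- st$order$gene[k]
    rows[[g]] <- tibble(gene = g, scaffold = "locus_scaffold",
                        start = pos, end = pos + lens[[g]] - 1L,
                        strand = st$order$strand[k])
    pos <- pos + lens[[g]] + gap
  }
  salv <- sort(st$salvaged)
  if (length(salv) > 0) {
    per <- if (two_gene_salvage) 2L else 1L
    scaf_idx <- ceiling(seq_along(salv) / per)
    offs <- integer(max(scaf_idx))
    for (k in seq_along(salv)) {
      g <- salv[k]
      sc <- sprintf("salvage_scaffold_%d", scaf_idx[k])
      start <- offs[scaf_idx[k]] + 1L
      rows[[g]] <- tibble(gene = g, scaffold = sc,
                          start = start, end = start + lens[[g]] - 1L,
                          strand = "+")
      offs[scaf_idx[k]] <- start + lens[[g]] + gap - 1L
    }
  }
  plen <- nchar(st$seqs[[paralog_id]])
  rows[[paralog_id]] <- tibble(gene = paralog_id, scaffold = "paralog_scaffold",
                               start = 1L, end = plen, strand = "+")
  bind_rows(rows)
}

validate_sim_truth <- function(truth, locus) {
  for (ev in truth$events) {
    both <- intersect(ev$lost, ev$salvaged)
    if (length(both) > 0) abort("truth invariant violated: lost & salvaged")
    interval_genes <- locus$gene[seq(ev$interval[1], ev$interval[2])]
    if (!all(c(ev$lost, ev$salvaged) %in% interval_genes)) {
      abort("truth invariant violated: fate outside the inverted interval")
    }
  }
  invisible(truth)
}

#' Expected root-to-tip distances implied by the simulation truth
#'
#' Sums branch length times per-gene effective rate over the path from the
#' ingroup stem node (where the outgroup attaches) to each ingroup tip.
#'
#' @param sim a `locus_sim`.
#' @return Tibble with columns `gene`, `species`, `expected_root_to_tip`.
#' @export
truth_root_to_tip <- function(sim) {
  tree <- sim$tree
  cfg <- sim$config
  ntip <- length(tree$tip.label)
  ingroup <- setdiff(tree$tip.label, cfg$outgroup)
  stem <- ape::getMRCA(tree, ingroup)
  rates <- sim$truth$rates
  lens <- setNames(tree$edge.length,
                   vapply(tree$edge[, 2], function(v) node_name(tree, v),
                          character(1)))
  base_rate <- setNames(cfg$locus$base_rate, cfg$locus$gene)
  out <- list()
  for (sp in ingroup) {
    path <- ape::nodepath(tree, stem, match(sp, tree$tip.label))
    branch_ids <- vapply(path[-1], function(v) node_name(tree, v), character(1))
    for (g in cfg$locus$gene) {
      mult <- rates |>
        filter(.data$gene == g, .data$branch %in% branch_ids)
      if (!all(mult$present)) next
      m <- setNames(mult$multiplier, mult$branch)
      out[[paste(sp, g)]] <- tibble(
        gene = g, species = sp,
        expected_root_to_tip = sum(lens[branch_ids] * base_rate[[g]] *
                                     m[branch_ids])
      )
    }
  }
  bind_rows(out)
}

#' @export
print.locus_sim <- function(x, ...) {
  cat("<locus_sim>\n")
  cat(sprintf("  %d species, %d gene records, %d reads, %d disruption event(s)\n",
              length(unique(x$genomes$species)), nrow(x$sequences),
              nrow(x$reads), length(x$truth$events)))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  for (ev in x$events) {
    cat(sprintf("  event on '%s': interval [%d, %d], %d lost, %d salvaged\n",
                ev$branch, ev$interval[1], ev$interval[2],
                length(ev$lost), length(ev$salvaged)))
  }
  invisible(x)
}

#' Write simulator outputs to disk
#'
#' Writes one FASTA (record ids `species|gene|scaffold`) and one FASTQ per
#' species, a gene-order TSV per species, the tree as newick and the truth log
#' as JSON.
#'
#' @param sim a `locus_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in unique(sim$genomes$species)) {
    sq <- filter(sim$sequences, .data$species == sp)
    dna <- Biostrings::DNAStringSet(setNames(sq$seq,
             paste(sp, sq$gene, sq$scaffold, sep = "|")))
    Biostrings::writeXStringSet(dna, file.path(dir, paste0(sp, ".fasta")))
    rd <- filter(sim$reads, .data$species == sp)
    writeLines(
      as.vector(rbind(paste0("@", rd$read_id), rd$seq, "+", rd$qual)),
      file.path(dir, paste0(sp, ".fastq"))
    )
    write_genome_table(filter(sim$genomes, .data$species == sp)[, -1],
                       file.path(dir, paste0(sp, "_genes.tsv")))
  }
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_sim_truth(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write / read the simulation truth log as JSON
#'
#' The round trip is lossless: `read_sim_truth(write_sim_truth(x, f))` equals
#' `x`.
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @return `path` (writer) or the `sim_truth` (reader).
#' @export
write_sim_truth <- function(truth, path) {
  payload <- list(
    events = lapply(truth$events, function(ev) list(
      branch = ev$branch, interval = ev$interval,
      lost = as.list(ev$lost), salvaged = as.list(ev$salvaged)
    )),
    rates = truth$rates,
    lost = as.list(truth$lost), salvaged = as.list(truth$salvaged),
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  events <- x$events
  if (is.data.frame(events)) {
    events <- lapply(seq_len(nrow(events)), function(i) list(
      branch = events$branch[i],
      interval = as.integer(events$interval[[i]]),
      lost = as.character(unlist(events$lost[[i]])),
      salvaged = as.character(unlist(events$salvaged[[i]]))
    ))
  } else {
    events <- lapply(events, function(ev) list(
      branch = ev$branch, interval = as.integer(unlist(ev$interval)),
      lost = as.character(unlist(ev$lost)),
      salvaged = as.character(unlist(ev$salvaged))
    ))
  }
  structure(list(
    events = events,
    rates = as_tibble(x$rates),
    lost = as.character(unlist(x$lost)),
    salvaged = as.character(unlist(x$salvaged)),
    seed = as.integer(x$seed)
  ), class = "sim_truth")
}
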