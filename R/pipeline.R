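# End-to-end orchestration: simulate -> detect -> synteny -> rates, with
# truth-based recovery scoring in synthetic mode.

#' Pipeline run configuration
#'
#' Exactly one of `sim` (a [sim_config()], synthetic mode) or `inputs` (paths
#' to real gene-order tables / FASTA / tree files) must be given.
#'
#' @param sim a [sim_config()] for synthetic mode.
#' @param inputs named list of file paths for real-data mode (not used by
#'   the bundled examples, which run synthetic or fixture analyses).
#' @param thresholds a [pipeline_thresholds()].
#' @param seed integer seed recorded in the report (the simulator uses the
#'   seed embedded in `sim`).
#' @param stages character subset of `c("detect", "synteny", "rates")`.
#' @param bait_species species whose sequences serve as baits; default: the
#'   species with the most annotated genes (ties broken alphabetically).
#' @param use_truth_fates if `TRUE`, skip the detection cascade and take
#'   presence/fates from the simulation truth (fast path for calibration
#'   studies of the rates stage).
#' @param out_dir optional output directory; stage outputs are cached there
#'   keyed by the configuration hash and reused on re-runs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       thresholds = pipeline_thresholds(),
                       seed = NULL,
                       stages = c("detect", "synteny", "rates"),
                       bait_species = NULL,
                       use_truth_fates = FALSE,
                       out_dir = NULL) {
  if (is.null(sim) == is.null(inputs)) {
    abort("exactly one of `sim` (synthetic mode) or `inputs` must be given")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- structure(list(sim = sim, inputs = inputs, thresholds = thresholds,
                        seed = seed %||% (if (!is.null(sim)) sim$seed else 1L),
                        stages = stages, bait_species = bait_species,
                        use_truth_fates = isTRUE(use_truth_fates),
                        out_dir = out_dir),
                   class = "run_config")
  cfg$hash <- rlang::hash(cfg[c("sim", "inputs", "thresholds", "seed",
                                "stages", "bait_species", "use_truth_fates")])
  cfg
}

# fates implied by the simulation truth, per ingroup species
truth_fates <- function(sim) {
  tree <- sim$tree
  cfg <- sim$config
  tips <- setdiff(tree$tip.label, cfg$outgroup)
  root <- length(tree$tip.label) + 1L
  out <- list()
  for (sp in tips) {
    path <- ape::nodepath(tree, root, match(sp, tree$tip.label))
    anc <- vapply(path[-1], function(v) node_name(tree, v), character(1))
    lost <- character(0); salv <- character(0)
    for (ev in sim$truth$events) {
      if (ev$branch %in% anc) {
        lost <- union(lost, ev$lost)
        salv <- union(salv, ev$salvaged)
      }
    }
    out[[sp]] <- tibble(
      species = sp, gene = cfg$locus$gene,
      fate = ifelse(cfg$locus$gene %in% lost, "lost",
                    ifelse(cfg$locus$gene %in% salv, "salvaged",
                           "retained_in_locus"))
    )
  }
  bind_rows(out)
}

# choose baits for one gene from the per-species sequence table
make_baits <- function(sequences, gene, paralog_id, bait_species,
                       focal_species = NA_character_) {
  seq_of <- function(sp, g) {
    s <- sequences$seq[sequences$species == sp & sequences$gene == g]
    if (length(s) == 1) s else NULL
  }
  ortho <- seq_of(bait_species, gene)
  if (is.null(ortho)) {
    donors <- sort(unique(sequences$species[sequences$gene == gene]))
    donors <- setdiff(donors, focal_species)
    if (length(donors) == 0) return(NULL)
    ortho <- seq_of(donors[1], gene)
  }
  para <- seq_of(bait_species, paralog_id) %||% {
    donors <- sort(unique(sequences$species[sequences$gene == paralog_id]))
    seq_of(donors[1], paralog_id)
  }
  panel_rows <- list()
  for (sp in sort(unique(sequences$species))) {
    if (!is.na(focal_species) && sp == focal_species) next
    g_seq <- seq_of(sp, gene)
    if (!is.null(g_seq)) {
      panel_rows[[paste(sp, "t")]] <- tibble(
        id = paste0(sp, "|", gene), family = "target",
        protein = translate_six_frames(g_seq)$protein[1]
      )
    }
    p_seq <- seq_of(sp, paralog_id)
    if (!is.null(p_seq)) {
      panel_rows[[paste(sp, "p")]] <- tibble(
        id = paste0(sp, "|", paralog_id), family = "paralog",
        protein = translate_six_frames(p_seq)$protein[1]
      )
    }
  }
  list(ortholog_nt = ortho,
       ortholog_aa = translate_six_frames(ortho)$protein[1],
       paralog_nt = para,
       panel = bind_rows(panel_rows))
}

#' Run the full analysis pipeline
#'
#' In synthetic mode: simulates the locus, runs the detection cascade for
#' every locus gene in every species, the synteny/fate analysis per species,
#' and the root-to-tip rate comparison of salvaged vs intact-locus genes,
#' and scores recovery against the simulation truth.
#'
#' @param config a [run_config()].
#' @return Object of class `run_report`: list with `presence` (detection
#'   records), `presence_matrix`, `reports` (per-species
#'   `disruption_report`s), `rates` (a `rate_table`), `comparison` (a
#'   `group_comparison` or `NULL`), `recovery` (synthetic mode only),
#'   `config`, `seed`, `hash`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  if (is.null(config$sim)) {
    abort("real-input mode expects pre-parsed tables; use the module functions directly (see the methods vignette)")
  }
  cache_get <- function(stage) {
    if (is.null(config$out_dir)) return(NULL)
    f <- file.path(config$out_dir, sprintf("cache_%s_%s.rds",
                                           config$hash, stage))
    if (file.exists(f)) readRDS(f) else NULL
  }
  cache_put <- function(stage, value) {
    if (is.null(config$out_dir)) return(invisible(NULL))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(value, file.path(config$out_dir, sprintf("cache_%s_%s.rds",
                                                     config$hash, stage)))
  }

  sim <- cache_get("sim") %||% simulate_locus(config$sim)
  cache_put("sim", sim)
  cfg <- sim$config
  paralog_id <- paste0(cfg$target_gene, "_paralog")
  species <- setdiff(sim$tree$tip.label, cfg$outgroup)
  reference_order <- cfg$locus[, c("gene", "strand")]
  th <- config$thresholds

  # detection ---------------------------------------------------------------
  if (config$use_truth_fates || !"detect" %in% config$stages) {
    tf <- truth_fates(sim)
    presence <- tf |>
      mutate(status = ifelse(.data$fate == "lost", "not_detected",
                             "detected"),
             tier = ifelse(.data$fate == "lost", NA_character_,
                           "annotation")) |>
      select("gene", "species", "tier", "status")
  } else {
    presence <- cache_get("detect")
    if (is.null(presence)) {
      # bait donor: the (non-outgroup) species with the fullest annotation,
      # mirroring the use of an intact close relative as the search bait
      counts <- sim$genomes |>
        filter(.data$species != cfg$outgroup) |>
        dplyr::count(.data$species)
      bait_species <- config$bait_species %||%
        sort(counts$species[counts$n == max(counts$n)])[1]
      baits_by_gene <- lapply(setNames(cfg$locus$gene, cfg$locus$gene),
                              function(g) {
        make_baits(sim$sequences, g, paralog_id, bait_species)
      })
      rows <- list()
      for (sp in species) {
        genome_sp <- filter(sim$genomes, .data$species == sp)
        seq_sp <- filter(sim$sequences, .data$species == sp)
        assembly <- setNames(seq_sp$seq, seq_sp$gene)
        reads_sp <- filter(sim$reads, .data$species == sp)[, c("read_id",
                                                               "seq")]
        for (g in cfg$locus$gene) {
          baits <- baits_by_gene[[g]]
          if (is.null(baits)) next
          rows[[paste(sp, g)]] <- call_gene_status(
            g, sp, genome_sp, assembly, reads_sp, baits, th
          )
        }
      }
      presence <- bind_rows(rows)
      cache_put("detect", presence)
    }
  }
  pm <- presence_matrix(presence, gene_order = cfg$locus$gene)

  # synteny / fates ----------------------------------------------------------
  reports <- list()
  if ("synteny" %in% config$stages) {
    for (sp in species) {
      genome_sp <- filter(sim$genomes, .data$species == sp,
                          .data$gene != paralog_id)
      placements <- map_to_reference(reference_order, genome_sp)
      blocks <- find_blocks(reference_order, placements)
      pres_sp <- filter(presence, .data$species == sp)
      reports[[sp]] <- classify_fates(reference_order, placements, pres_sp,
                                      blocks, species = sp,
                                      max_salvage_block =
                                        th$max_salvage_block)
    }
  }

  # rates --------------------------------------------------------------------
  rates <- NULL; comparison <- NULL
  if ("rates" %in% config$stages) {
    rates <- cache_get("rates")
    if (is.null(rates)) {
      fates <- if (length(reports) > 0) {
        bind_rows(lapply(reports, function(r) {
          mutate(r$fates, species = r$species)
        }))
      } else {
        truth_fates(sim)
      }
      groups <- fates |>
        mutate(group = dplyr::case_when(
          .data$fate == "salvaged" ~ "salvaged_locus",
          .data$fate == "retained_in_locus" ~ "intact_locus",
          TRUE ~ NA_character_
        )) |>
        filter(!is.na(.data$group)) |>
        select("gene", "species", "group")
      alignments <- lapply(setNames(cfg$locus$gene, cfg$locus$gene),
                           function(g) {
        sq <- filter(sim$sequences, .data$gene == g)
        aligned_set(sq$species, sq$seq, "nucleotide")
      })
      rates <- rate_table(alignments, sim$tree, cfg$outgroup,
                          groups = groups, model = cfg$subst_model,
                          kappa = cfg$kappa)
      cache_put("rates", rates)
    }
    disrupted_sp <- rates |>
      filter(.data$group == "salvaged_locus") |>
      pull("species") |> unique()
    n_salv <- rates |>
      filter(.data$group == "salvaged_locus") |>
      pull("gene") |> unique()
    if (length(disrupted_sp) > 0 && length(n_salv) >= 3) {
      comparison <- tryCatch(
        compare_rate_groups(rates, species = disrupted_sp),
        error = function(e) NULL
      )
    }
  }

  # recovery vs truth ---------------------------------------------------------
  tf <- truth_fates(sim)
  recovery <- NULL
  if (length(reports) > 0 && !config$use_truth_fates) {
    called <- bind_rows(lapply(reports, function(r) {
      mutate(r$fates, species = r$species)
    }))
    joined <- left_join(called, tf, by = c("gene", "species"),
                        suffix = c("_called", "_true"))
    fate_accuracy <- mean(joined$fate_called == joined$fate_true)
    truth_present <- tf$fate != "lost"
    called_present <- presence$status[match(paste(tf$gene, tf$species),
                                            paste(presence$gene,
                                                  presence$species))] ==
      "detected"
    tp <- sum(called_present & truth_present)
    precision <- if (sum(called_present) == 0) NA_real_
                 else tp / sum(called_present)
    recall <- if (sum(truth_present) == 0) NA_real_
              else tp / sum(truth_present)
    recovery <- list(fate_accuracy = fate_accuracy, precision = precision,
                     recall = recall)
  }
  if (!is.null(rates)) {
    expected <- truth_root_to_tip(sim)
    obs <- left_join(as_tibble(rates), expected, by = c("gene", "species")) |>
      filter(!is.na(.data$expected_root_to_tip),
             .data$expected_root_to_tip > 0) |>
      mutate(rel_error = abs(.data$root_to_tip -
                               .data$expected_root_to_tip) /
               .data$expected_root_to_tip)
    recovery <- c(recovery %||% list(),
                  list(root_to_tip_within_10pct = mean(obs$rel_error <= 0.10),
                       median_rel_error = stats::median(obs$rel_error)))
  }

  structure(list(
    presence = presence, presence_matrix = pm, reports = reports,
    rates = rates, comparison = comparison, recovery = recovery,
    truth = sim$truth, sim = sim,
    config = config, seed = config$seed, hash = config$hash
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  seed %s, config hash %s\n", x$seed, x$hash))
  if (!is.null(x$presence)) {
    cat(sprintf("  detection: %d records, %d detected\n",
                nrow(x$presence),
                sum(x$presence$status == "detected")))
  }
  if (length(x$reports) > 0) {
    cat(sprintf("  synteny reports for %d species\n", length(x$reports)))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  salvaged vs intact rates: %s test, p = %.4g\n",
                x$comparison$test, x$comparison$p.value))
  }
  if (!is.null(x$recovery)) {
    cat("  recovery:",
        paste(sprintf("%s = %.3f", names(x$recovery),
                      unlist(x$recovery)), collapse = ", "), "\n")
  }
  invisible(x)
}
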