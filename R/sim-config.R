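#' Default species tree for the locus simulator
#'
#' A small bird-like rooted phylogeny with an alligator-like outgroup and six
#' ingroup species: two galliform-like sister tips (`chicken`, `quail`), an
#' anseriform-like tip (`duck`), two passeriform-like tips (`zebrafinch`,
#' `crow`) and a basal palaeognath-like tip (`ostrich`). The ingroup is
#' clock-like (all ingroup tips lie at 0.15 expected substitutions/site from
#' the ingroup root at base rate 1), so that under a uniform rate the
#' root-to-tip statistic is exchangeable across tips. Internal nodes are
#' labelled so branches can be addressed by the name of their child node.
#'
#' @return An [ape::read.tree()] phylogeny.
#' @export
default_bird_tree <- function() {
  txt <- paste0(
    "(((((chicken:0.04,quail:0.04)galliformes:0.03,duck:0.07)",
    "galloanserae:0.03,(zebrafinch:0.05,crow:0.05)passeriformes:0.05)",
    "neognaths:0.05,ostrich:0.15)birds:0.02,alligator:0.3)root;"
  )
  ape::read.tree(text = txt)
}

#' Default locus description for the simulator
#'
#' @param n_genes number of genes in the conserved locus.
#' @param length_nt gene length in nucleotides (must be a multiple of 3).
#' @param base_rate per-gene substitution rate relative to the tree's branch
#'   lengths. Conserved coding genes evolve well below the neutral rate; the
#'   default of 0.5 keeps orthologs of distant ingroup species at roughly
#'   85-90% nucleotide identity, the regime the detection thresholds assume.
#' @return A tibble with columns `gene`, `strand`, `length_nt`, `base_rate`.
#' @export
default_locus <- function(n_genes = 20, length_nt = 1500, base_rate = 0.5) {
  tibble(
    gene = sprintf("G%02d", seq_len(n_genes)),
    strand = rep_len(c("+", "+", "-", "+"), n_genes),
    length_nt = length_nt,
    base_rate = base_rate
  )
}

#' Configuration for the locus-evolution simulator
#'
#' Describes a conserved multi-gene locus evolving along a fixed species tree.
#' On designated branches a disruption event applies an inversion to a locus
#' interval; each gene of the interval is then lost (probability `p_loss`) or,
#' with probability `p_salvage` among the survivors, relocated ("salvaged") to
#' an isolated scaffold where it evolves at `rho` times its base rate. A
#' diverged paralog of `target_gene` is present in every species to exercise
#' the paralog filter of the detection cascade.
#'
#' @param tree rooted phylogeny with branch lengths in expected
#'   substitutions/site at base rate 1: a newick string or an `ape::phylo`.
#'   Needs at least two tips; `outgroup` must be one of them.
#' @param locus tibble with columns `gene`, `strand` (`+`/`-`), `length_nt`
#'   (multiple of 3) and `base_rate` (>= 0), in locus order.
#' @param flank_genes number of genes at each end of the locus that random
#'   disruption intervals never touch.
#' @param disruption_branches character vector of branch ids (child node or
#'   tip labels) that carry a forced disruption event, or `NULL`.
#' @param p_disrupt per-branch disruption probability for branches not listed
#'   in `disruption_branches`.
#' @param inversion_interval explicit `c(i, j)` interval of locus indices for
#'   every event, or `NULL` to draw uniformly inside the flank bounds.
#' @param p_loss probability that a gene of the disrupted interval is lost.
#' @param p_salvage probability that a surviving interval gene is relocated to
#'   an isolated scaffold (otherwise it stays, inverted, in the locus).
#' @param rho rate multiplier (>= 1) applied to salvaged genes from the
#'   disruption branch onwards.
#' @param subst_model `"JC69"` or `"K80"`.
#' @param kappa transition/transversion rate ratio for K80.
#' @param target_gene the locus gene whose paralog is simulated (the
#'   headline gene of the detection analysis). Defaults to the middle gene.
#' @param paralog_divergence expected substitutions/site separating the
#'   paralog family from the target family before the species-tree root.
#' @param two_gene_salvage if `TRUE`, consecutive salvaged genes are placed
#'   two per scaffold instead of one per scaffold.
#' @param read_len,coverage,err_rate shotgun read simulation: read length in
#'   nt, fold coverage per gene, and uniform per-base error probability.
#' @param outgroup tip used to root the rate analysis.
#' @param seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tree = default_bird_tree(),
                       locus = default_locus(),
                       flank_genes = 4,
                       disruption_branches = NULL,
                       p_disrupt = 0,
                       inversion_interval = NULL,
                       p_loss = 0.5,
                       p_salvage = 1,
                       rho = 3,
                       subst_model = c("JC69", "K80"),
                       kappa = 2,
                       target_gene = NULL,
                       paralog_divergence = 0.4,
                       two_gene_salvage = FALSE,
                       read_len = 100,
                       coverage = 5,
                       err_rate = 0.005,
                       outgroup = "alligator",
                       seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo or newick text")
  if (length(tree$tip.label) < 2) abort("tree must have at least 2 tips")
  if (!outgroup %in% tree$tip.label) {
    abort(sprintf("outgroup '%s' is not a tip of the tree", outgroup))
  }
  locus <- as_tibble(locus)
  needed <- c("gene", "strand", "length_nt", "base_rate")
  if (!all(needed %in% names(locus))) {
    abort(paste("`locus` needs columns", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(locus$gene)) abort("locus gene ids must be unique")
  if (any(locus$length_nt <= 0) || any(locus$length_nt %% 3 != 0)) {
    abort("gene lengths must be positive multiples of 3")
  }
  if (any(locus$base_rate < 0)) abort("base rates must be >= 0")
  if (!all(locus$strand %in% c("+", "-"))) abort("strands must be '+' or '-'")
  for (p in c("p_disrupt", "p_loss", "p_salvage", "err_rate")) {
    stopifnot_scalar_number(get(p), p, 0, 1)
  }
  stopifnot_scalar_number(rho, "rho", min = 1)
  stopifnot_scalar_number(paralog_divergence, "paralog_divergence", min = 0)
  stopifnot_scalar_number(read_len, "read_len", min = 1)
  stopifnot_scalar_number(coverage, "coverage")
  if (coverage <= 0) abort("`coverage` must be > 0")
  subst_model <- match.arg(subst_model)
  n <- nrow(locus)
  if (flank_genes < 0 || 2 * flank_genes >= n) {
    abort("`flank_genes` must leave at least one disruptable gene")
  }
  if (!is.null(inversion_interval)) {
    ij <- as.integer(inversion_interval)
    if (length(ij) != 2 || ij[1] > ij[2] || ij[1] < 1 || ij[2] > n) {
      abort("`inversion_interval` must be c(i, j) with 1 <= i <= j <= n_genes")
    }
    if (ij[1] <= flank_genes || ij[2] > n - flank_genes) {
      abort("`inversion_interval` intrudes into the protected flanks")
    }
  }
  target_gene <- target_gene %||% locus$gene[ceiling(n / 2)]
  if (!target_gene %in% locus$gene) abort("`target_gene` not in the locus")
  branch_ids <- tree_branch_ids(tree)
  if (!is.null(disruption_branches) &&
      !all(disruption_branches %in% branch_ids)) {
    abort("unknown branch id in `disruption_branches`")
  }
  structure(
    list(tree = tree, locus = locus, flank_genes = as.integer(flank_genes),
         disruption_branches = disruption_branches, p_disrupt = p_disrupt,
         inversion_interval = if (is.null(inversion_interval)) NULL
                              else as.integer(inversion_interval),
         p_loss = p_loss, p_salvage = p_salvage, rho = rho,
         subst_model = subst_model, kappa = kappa,
         target_gene = target_gene,
         paralog_divergence = paralog_divergence,
         two_gene_salvage = isTRUE(two_gene_salvage),
         read_len = as.integer(read_len), coverage = coverage,
         err_rate = err_rate, outgroup = outgroup, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# label every node so branches can be addressed as "branch ending in node X";
# unlabelled internal nodes get stable numeric names
label_nodes <- function(tree) {
  nn <- tree$Nnode
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    lab <- tree$node.label %||% rep("", nn)
    miss <- which(lab == "")
    lab[miss] <- sprintf("node%d", miss + length(tree$tip.label))
    tree$node.label <- lab
  }
  tree
}

node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ifelse(node <= ntip, tree$tip.label[node], tree$node.label[node - ntip])
}

# branch ids = child-node names of every edge
tree_branch_ids <- function(tree) {
  tree <- label_nodes(tree)
  vapply(tree$edge[, 2], function(v) node_name(tree, v), character(1))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes, %d tips, model %s, seed %d\n",
              nrow(x$locus), length(x$tree$tip.label), x$subst_model, x$seed))
  cat(sprintf("  target gene %s (paralog divergence %.2f), rho = %.2f\n",
              x$target_gene, x$paralog_divergence, x$rho))
  invisible(x)
}
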