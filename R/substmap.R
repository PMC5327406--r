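# Alignment-level statistics: gap trimming, pairwise identity/similarity,
# parsimony ancestral reconstruction, and conservative/non-conservative
# substitution mapping.

#' Build or read an aligned sequence set
#'
#' @param ids,seqs record ids and equal-length aligned sequences (gap `-`).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Tibble (`id`, `seq`) of class `aligned_set` with an `alphabet`
#'   attribute.
#' @export
aligned_set <- function(ids, seqs, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (anyDuplicated(ids)) abort("alignment ids must be unique")
  if (length(unique(nchar(seqs))) > 1) {
    abort("aligned sequences must have equal length")
  }
  out <- tibble(id = as.character(ids), seq = toupper(seqs))
  attr(out, "alphabet") <- alphabet
  class(out) <- c("aligned_set", class(out))
  out
}

#' @rdname aligned_set
#' @param path FASTA file of aligned sequences.
#' @export
read_alignment <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "protein") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  aligned_set(names(x), as.character(x), alphabet)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
}

aln_from_matrix <- function(aln, m) {
  out <- aligned_set(aln$id, apply(m, 1, paste, collapse = ""),
                     attr(aln, "alphabet"))
  out
}

#' Remove gapped columns from an alignment
#'
#' `any_gap` drops every column containing at least one gap; `majority_gap`
#' drops columns where more than half the rows are gaps.
#'
#' @param aln an [aligned_set()].
#' @param mode `"any_gap"` (default) or `"majority_gap"`.
#' @return The trimmed `aligned_set`; a warning is raised if nothing is left.
#' @export
strip_gap_columns <- function(aln, mode = c("any_gap", "majority_gap")) {
  mode <- match.arg(mode)
  m <- aln_matrix(aln)
  if (ncol(m) == 0) return(aln)
  gap_frac <- colMeans(m == "-")
  keep <- if (mode == "any_gap") gap_frac == 0 else gap_frac <= 0.5
  if (!any(keep)) {
    warn("all columns removed by gap stripping; alignment is empty")
    return(aln_from_matrix(aln, m[, 0, drop = FALSE]))
  }
  aln_from_matrix(aln, m[, keep, drop = FALSE])
}

#' Pairwise percent identity of two aligned rows
#'
#' 100 x matches / comparable columns, where comparable columns are those in
#' which both rows carry a residue (no gap). Symmetric; `NA` when there is
#' nothing to compare.
#'
#' @param a,b equal-length aligned sequences.
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("aligned rows must have equal length")
  va <- chars(a); vb <- chars(b)
  comp <- va != "-" & vb != "-"
  if (!any(comp)) return(NA_real_)
  100 * sum(va[comp] == vb[comp]) / sum(comp)
}

#' Pairwise percent similarity under a substitution matrix
#'
#' Like [percent_identity()] but mismatches with a strictly positive
#' substitution-matrix score (conservative replacements) also count. Always
#' at least the identity.
#'
#' @param a,b equal-length aligned protein sequences.
#' @param matrix substitution matrix (default BLOSUM62).
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
percent_similarity <- function(a, b, matrix = "BLOSUM62") {
  S <- resolve_matrix(matrix)
  if (nchar(a) != nchar(b)) abort("aligned rows must have equal length")
  va <- chars(a); vb <- chars(b)
  comp <- va != "-" & vb != "-"
  if (!any(comp)) return(NA_real_)
  va <- va[comp]; vb <- vb[comp]
  ok <- va == vb | S[cbind(va, vb)] > 0
  100 * sum(ok) / length(va)
}

#' All pairwise identities and similarities of an alignment
#'
#' @param aln an [aligned_set()] (trimmed; protein for similarity).
#' @param matrix substitution matrix for the similarity.
#' @return Long tibble `id1`, `id2`, `identity`, `similarity` (similarity is
#'   `NA` for nucleotide alignments).
#' @export
identity_matrix <- function(aln, matrix = "BLOSUM62") {
  ids <- aln$id
  protein <- identical(attr(aln, "alphabet"), "protein")
  pairs <- expand.grid(i = seq_along(ids), j = seq_along(ids)) |>
    filter(.data$i < .data$j)
  bind_rows(lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$i[k]; j <- pairs$j[k]
    tibble(id1 = ids[i], id2 = ids[j],
           identity = percent_identity(aln$seq[i], aln$seq[j]),
           similarity = if (protein)
             percent_similarity(aln$seq[i], aln$seq[j], matrix)
           else NA_real_)
  }))
}

# ---------------------------------------------------------------------------
# Fitch parsimony ancestral reconstruction

# neighbour lists of a phylo tree (undirected)
tree_neighbours <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  nb <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

# Fitch bottom-up state sets with `root` as traversal root; returns the set
# at `root` and the parsimony cost. tip_states: list of character vectors
# (a tip with missing data contributes the full alphabet).
fitch_root_set <- function(nb, root, tip_states, ntip, alphabet) {
  cost <- 0L
  rec <- function(v, parent) {
    if (v <= ntip) return(tip_states[[v]])
    sets <- lapply(setdiff(nb[[v]], parent), rec, parent = v)
    acc <- sets[[1]]
    for (s in sets[-1]) {
      inter <- intersect(acc, s)
      if (length(inter) > 0) acc <- inter
      else { acc <- union(acc, s); cost <<- cost + 1L }
    }
    acc
  }
  set <- rec(root, 0L)
  list(set = set, cost = cost)
}

#' Reconstruct an ancestral sequence by Fitch parsimony
#'
#' Computes, per alignment column, the Fitch state set at `node` (the tree is
#' traversed with `node` as root, so the set contains the states compatible
#' with some most-parsimonious reconstruction at that node). Ambiguity is
#' resolved deterministically: (1) the candidate state most frequent among
#' the tip states of the column; (2) for proteins, the candidate with the
#' highest summed BLOSUM62 score against the tip states; (3) alphabetical
#' order. Gaps and ambiguity codes at tips are treated as missing data.
#'
#' @param aln an [aligned_set()] whose ids cover the tree's tips.
#' @param tree rooted `ape::phylo` (node labels used to address `node`).
#' @param node internal node: a node label or an ape node number.
#' @return List of class `ancestral_reconstruction`: `sequence`, `node`,
#'   `cost` (total parsimony cost), `ambiguous` (columns with > 1 candidate).
#' @export
reconstruct_ancestor <- function(aln, tree, node) {
  tree <- label_nodes(tree)
  ntip <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, aln$id)
  if (length(missing_tips) > 0) {
    abort(sprintf("tip '%s' is missing from the alignment", missing_tips[1]))
  }
  if (is.character(node)) {
    k <- match(node, tree$node.label)
    if (is.na(k)) abort(sprintf("unknown internal node '%s'", node))
    node_num <- ntip + k
  } else {
    node_num <- as.integer(node)
    if (node_num <= ntip) abort("`node` must be an internal node")
  }
  protein <- identical(attr(aln, "alphabet"), "protein")
  alphabet <- if (protein) AA20 else DNA_BASES
  S <- if (protein) blosum62_matrix() else NULL
  m <- aln_matrix(aln)[match(tree$tip.label, aln$id), , drop = FALSE]
  nb <- tree_neighbours(tree)
  n_col <- ncol(m)
  out <- character(n_col)
  total_cost <- 0L
  ambiguous <- integer(0)
  for (j in seq_len(n_col)) {
    col <- m[, j]
    tip_states <- lapply(col, function(s) {
      if (s %in% alphabet) s else alphabet
    })
    fr <- fitch_root_set(nb, node_num, tip_states, ntip, alphabet)
    total_cost <- total_cost + fr$cost
    cand <- sort(fr$set)
    if (length(cand) > 1) {
      ambiguous <- c(ambiguous, j)
      obs <- col[col %in% alphabet]
      freq <- vapply(cand, function(s) sum(obs == s), integer(1))
      cand <- cand[freq == max(freq)]
      if (length(cand) > 1 && protein) {
        sim <- vapply(cand, function(s) sum(S[s, obs]), numeric(1))
        cand <- cand[sim == max(sim)]
      }
      cand <- sort(cand)[1]
    }
    out[j] <- cand
  }
  structure(list(sequence = paste(out, collapse = ""),
                 node = node_name(tree, node_num),
                 cost = total_cost, ambiguous = ambiguous),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("<ancestral_reconstruction> node %s, cost %d, %d ambiguous column(s)\n",
              x$node, x$cost, length(x$ambiguous)))
  invisible(x)
}

#' Map substitutions between an ancestor and a descendant
#'
#' Labels every aligned column `identical`, `conservative` (substitution
#' with strictly positive matrix score), `nonconservative` (score <= 0) or
#' `indel` (exactly one of the pair gapped). Columns gapped in both rows are
#' skipped with a warning.
#'
#' @param ancestor,descendant equal-length aligned sequences.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param ancestor_id,descendant_id ids recorded in the result.
#' @return Tibble of class `substitution_map`: `column`, `ancestor`,
#'   `descendant`, `label`, with attributes `matrix_name`, `ancestor_id`,
#'   `descendant_id`.
#' @export
map_substitutions <- function(ancestor, descendant, matrix = "BLOSUM62",
                              ancestor_id = "ancestor",
                              descendant_id = "descendant") {
  S <- resolve_matrix(matrix)
  if (nchar(ancestor) != nchar(descendant)) {
    abort("aligned pair must have equal length")
  }
  va <- chars(ancestor); vb <- chars(descendant)
  both_gap <- va == "-" & vb == "-"
  if (any(both_gap)) {
    warn(sprintf("%d column(s) gapped in both rows skipped", sum(both_gap)))
  }
  keep <- which(!both_gap)
  label <- vapply(keep, function(j) {
    if (va[j] == "-" || vb[j] == "-") return("indel")
    if (va[j] == vb[j]) return("identical")
    if (S[va[j], vb[j]] > 0) "conservative" else "nonconservative"
  }, character(1))
  out <- tibble(column = keep, ancestor = va[keep], descendant = vb[keep],
                label = label)
  attr(out, "matrix_name") <- if (is.character(matrix)) matrix else "custom"
  attr(out, "ancestor_id") <- ancestor_id
  attr(out, "descendant_id") <- descendant_id
  class(out) <- c("substitution_map", class(out))
  out
}

#' @rdname map_substitutions
#' @param map a `substitution_map`.
#' @param path output TSV.
#' @export
write_substitution_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}
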