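# Likelihood machinery on a fixed topology: Felsenstein pruning under
# JC69/K80 with uniform base frequencies, coordinate-wise branch-length
# optimisation, the root-to-tip rate statistic, and the normality-gated
# two-sample comparison of salvaged vs intact-locus genes.

# 4x4 transition probability matrix at distance t
pmatrix <- function(t, model, kappa = 2) {
  if (model == "JC69") {
    pd <- jc69_p(t) / 3
    m <- matrix(pd, 4, 4)
    diag(m) <- 1 - 3 * pd
    return(m)
  }
  pr <- k80_probs(t, kappa)
  ts <- pr[["ts"]]; tv <- pr[["tv"]]
  same <- 1 - ts - 2 * tv
  # order A, C, G, T; transitions A<->G and C<->T
  matrix(c(same, tv,   ts,   tv,
           tv,   same, tv,   ts,
           ts,   tv,   same, tv,
           tv,   ts,   tv,   same), 4, 4, byrow = TRUE)
}

# site-pattern compression of an alignment restricted to the tree's tips;
# returns list(codes = ntip x npat integer matrix (NA for non-ACGT),
#              weights)
site_patterns <- function(tree, aln) {
  aln <- as_tibble(aln)
  miss <- setdiff(tree$tip.label, aln$id)
  if (length(miss) > 0) {
    abort(sprintf("tip '%s' is missing from the alignment", miss[1]))
  }
  seqs <- aln$seq[match(tree$tip.label, aln$id)]
  if (length(unique(nchar(seqs))) != 1) {
    abort("aligned sequences must have equal length")
  }
  if (nchar(seqs[1]) == 0) abort("alignment has zero columns")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  codes <- matrix(match(m, DNA_BASES), nrow = nrow(m))
  key <- apply(codes, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[uniq])))
  list(codes = codes[, uniq, drop = FALSE], weights = weights)
}

# conditional likelihoods at the tips: list over nodes of 4 x npat matrices
tip_partials <- function(codes) {
  ntip <- nrow(codes); npat <- ncol(codes)
  lapply(seq_len(ntip), function(i) {
    m <- matrix(0, 4, npat)
    ci <- codes[i, ]
    known <- !is.na(ci)
    m[cbind(ci[known], which(known))] <- 1
    m[, !known] <- 1          # missing data: all states possible
    m
  })
}

# postorder "down" partials for every node; returns list(partials, logscale)
down_partials <- function(tree, elen, tips, model, kappa) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  npat <- ncol(tips[[1]])
  partial <- vector("list", nn)
  partial[seq_len(ntip)] <- tips
  logscale <- rep(0, npat)
  edges <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    # accumulate child into parent lazily: initialise parent partial to 1
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    if (is.null(partial[[a]])) partial[[a]] <- matrix(1, 4, npat)
    P <- pmatrix(po$edge.length[e], model, kappa)
    partial[[a]] <- partial[[a]] * (P %*% partial[[b]])
    mx <- col_max4(partial[[a]])
    mx[mx < 1e-200] <- 1
    partial[[a]] <- partial[[a]] / rep(mx, each = 4)
    logscale <- logscale + log(mx)
  }
  list(partial = partial, logscale = logscale)
}

# columnwise max of a 4 x n matrix without apply()
col_max4 <- function(m) pmax(m[1, ], m[2, ], m[3, ], m[4, ])

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' JC69 or K80 with uniform base frequencies; non-ACGT symbols are treated
#' as missing data. Sites are pattern-compressed and partial likelihoods are
#' rescaled per node, so long low-divergence alignments are cheap and safe.
#'
#' @param tree rooted `ape::phylo` with branch lengths in
#'   substitutions/site.
#' @param aln nucleotide [aligned_set()] (or tibble `id`, `seq`) covering
#'   the tree's tips.
#' @param model `"JC69"` or `"K80"`.
#' @param kappa K80 transition/transversion ratio.
#' @return Log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(tree, aln, model = c("JC69", "K80"), kappa = 2) {
  model <- match.arg(model)
  sp <- site_patterns(tree, aln)
  tips <- tip_partials(sp$codes)
  dp <- down_partials(tree, tree$edge.length, tips, model, kappa)
  root <- length(tree$tip.label) + 1L
  site_l <- colSums(dp$partial[[root]] * 0.25)
  sum(sp$weights * (log(site_l) + dp$logscale))
}

# rescale a 4 x npat matrix, tracking the log of the scalers
rescale <- function(m, logscale) {
  mx <- col_max4(m)
  mx[mx <= 0 | mx > 1e200] <- 1
  list(m = m / rep(mx, each = 4), logscale = logscale + log(mx))
}

#' Fit branch lengths on a fixed topology by maximum likelihood
#'
#' Coordinate-wise Brent optimisation of each branch within
#' `bounds`, sweeping over all branches until the log-likelihood gain of a
#' sweep falls below `tol`. Partial likelihoods above and below the current
#' branch are recomputed before each one-dimensional optimisation, so the
#' log-likelihood is non-decreasing across updates.
#'
#' @inheritParams pruning_loglik
#' @param topology rooted `ape::phylo`; its branch lengths (if any) are
#'   ignored and refitted from `init`.
#' @param bounds branch-length search interval.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_sweeps sweep limit; exceeding it flags non-convergence.
#' @param init initial branch length.
#' @param brent_tol argument tolerance of each one-dimensional Brent search.
#' @return Object of class `branch_fit`: list with `tree` (lengths fitted),
#'   `loglik`, `sweeps`, `converged`, `model`, `logliks` (per sweep).
#' @export
fit_branch_lengths <- function(topology, aln, model = c("JC69", "K80"),
                               kappa = 2, bounds = c(1e-8, 10), tol = 1e-6,
                               max_sweeps = 100, init = 0.1,
                               brent_tol = 1e-8) {
  model <- match.arg(model)
  first_sweep <- TRUE
  tree <- topology
  tree$edge.length <- rep(init, nrow(tree$edge))
  sp <- site_patterns(tree, aln)
  tips <- tip_partials(sp$codes)
  w <- sp$weights
  npat <- length(w)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  loglik_now <- function() {
    dp <- down_partials(tree, tree$edge.length, tips, model, kappa)
    site_l <- colSums(dp$partial[[root]] * 0.25)
    sum(w * (log(site_l) + dp$logscale))
  }

  # "above" partial A[v]: likelihood of all data outside the subtree of v,
  # as a function of the state at v (computed fresh for one focal edge)
  children_of <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  parent_of <- function(v) {
    p <- tree$edge[tree$edge[, 2] == v, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  edge_index <- function(p, c) which(tree$edge[, 1] == p & tree$edge[, 2] == c)

  optimise_edge <- function(e, down) {
    p_node <- tree$edge[e, 1]; c_node <- tree$edge[e, 2]
    # B = above(p_node) * product over siblings of P %*% down[sib]
    B <- matrix(0.25, 4, npat)
    log_b <- rep(0, npat)
    v <- p_node
    # climb from p_node to the root collecting sibling contributions
    path <- list()
    while (!is.na(parent_of(v))) {
      path[[length(path) + 1]] <- v
      v <- parent_of(v)
    }
    # build A top-down: A[root] = pi; then descend the stored path
    A <- matrix(0.25, 4, npat); log_a <- rep(0, npat)
    for (v in rev(path)) {
      pv <- parent_of(v)
      sibs <- setdiff(children_of(pv), v)
      for (s in sibs) {
        Ps <- pmatrix(tree$edge.length[edge_index(pv, s)], model, kappa)
        A <- A * (Ps %*% down$partial[[s]])
      }
      Pv <- pmatrix(tree$edge.length[edge_index(pv, v)], model, kappa)
      A <- crossprod(Pv, A)
      r <- rescale(A, log_a); A <- r$m; log_a <- r$logscale
    }
    # siblings of c_node below p_node
    B <- A
    for (s in setdiff(children_of(p_node), c_node)) {
      Ps <- pmatrix(tree$edge.length[edge_index(p_node, s)], model, kappa)
      B <- B * (Ps %*% down$partial[[s]])
    }
    r <- rescale(B, log_a); B <- r$m; log_b <- r$logscale
    D <- down$partial[[c_node]]
    obj <- function(t) {
      P <- pmatrix(t, model, kappa)
      site_l <- colSums(B * (P %*% D))
      sum(w * (log(site_l) + log_b + down$logscale_node[[c_node]]))
    }
    # warm start: after the first sweep, search a window around the current
    # value and fall back to the full interval if the optimum hugs an
    # interior window edge
    cur <- tree$edge.length[e]
    win <- if (first_sweep) bounds else {
      c(max(bounds[1], cur / 4), min(bounds[2], 4 * cur + 0.02))
    }
    opt <- optimize(obj, interval = win, maximum = TRUE, tol = brent_tol)
    at_edge <- (opt$maximum - win[1] < 1e-7 && win[1] > bounds[1]) ||
      (win[2] - opt$maximum < 1e-7 && win[2] < bounds[2])
    if (at_edge) {
      opt <- optimize(obj, interval = bounds, maximum = TRUE, tol = brent_tol)
    }
    opt$maximum
  }

  # down partials with per-node accumulated logscale (needed per edge)
  down_with_node_scale <- function() {
    nn <- ntip + tree$Nnode
    partial <- vector("list", nn)
    partial[seq_len(ntip)] <- tips
    logscale_node <- vector("list", nn)
    for (i in seq_len(ntip)) logscale_node[[i]] <- rep(0, npat)
    po <- ape::reorder.phylo(tree, "postorder")
    for (e in seq_len(nrow(po$edge))) {
      a <- po$edge[e, 1]; b <- po$edge[e, 2]
      if (is.null(partial[[a]])) {
        partial[[a]] <- matrix(1, 4, npat)
        logscale_node[[a]] <- rep(0, npat)
      }
      P <- pmatrix(po$edge.length[e], model, kappa)
      partial[[a]] <- partial[[a]] * (P %*% partial[[b]])
      logscale_node[[a]] <- logscale_node[[a]] + logscale_node[[b]]
      r <- rescale(partial[[a]], logscale_node[[a]])
      partial[[a]] <- r$m; logscale_node[[a]] <- r$logscale
    }
    list(partial = partial, logscale_node = logscale_node)
  }

  ll <- loglik_now()
  lls <- ll
  sweeps <- 0L
  converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    for (e in seq_len(nrow(tree$edge))) {
      down <- down_with_node_scale()
      tree$edge.length[e] <- optimise_edge(e, down)
    }
    first_sweep <- FALSE
    ll_new <- loglik_now()
    lls <- c(lls, ll_new)
    if (ll_new - ll < tol) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  if (!converged) {
    warn(sprintf("branch-length fit did not converge after %d sweeps",
                 max_sweeps))
  }
  structure(list(tree = tree, loglik = ll, sweeps = sweeps,
                 converged = converged, model = model, logliks = lls),
            class = "branch_fit")
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("<branch_fit> %s, logLik %.4f after %d sweep(s)%s\n",
              x$model, x$loglik, x$sweeps,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Root-to-tip distance of a tip
#'
#' Sum of branch lengths on the path from a reference node to `species`.
#' With `from = "root"` the reference node is the tree's root; with
#' `from = "ingroup"` it is the ingroup stem node (the most recent common
#' ancestor of all non-outgroup tips), which is the identifiable proxy for
#' the outgroup/ingroup common ancestor under reversible models and the
#' reference used by the rates pipeline.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param species a tip label.
#' @param from `"root"` or `"ingroup"`.
#' @param outgroup outgroup tip (required for `from = "ingroup"`).
#' @return Distance in substitutions/site.
#' @export
root_to_tip <- function(tree, species, from = c("root", "ingroup"),
                        outgroup = NULL) {
  from <- match.arg(from)
  tip <- match(species, tree$tip.label)
  if (is.na(tip)) abort(sprintf("unknown tip '%s'", species))
  start <- length(tree$tip.label) + 1L
  if (from == "ingroup") {
    if (is.null(outgroup)) abort("`outgroup` is required for from = 'ingroup'")
    ingroup <- setdiff(tree$tip.label, outgroup)
    if (identical(species, outgroup)) {
      abort("root-to-tip from the ingroup stem is undefined for the outgroup")
    }
    start <- ape::getMRCA(tree, ingroup)
  }
  path <- ape::nodepath(tree, start, tip)
  if (length(path) < 2) return(0)
  sum(vapply(seq_len(length(path) - 1), function(k) {
    e <- which(tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1])
    tree$edge.length[e]
  }, numeric(1)))
}

#' Per-gene, per-species root-to-tip rate table
#'
#' Fits branch lengths for every gene alignment on the fixed topology
#' (pruned to the species with a sequence) and tabulates the root-to-tip
#' distance of every ingroup tip, measured from the ingroup stem node.
#'
#' @param alignments named list of nucleotide [aligned_set()]s, one per gene;
#'   ids are species names.
#' @param topology rooted `ape::phylo` covering all species.
#' @param outgroup outgroup tip label.
#' @param groups optional tibble `gene`, `species`, `group` merged into the
#'   result (`outside_locus` where missing).
#' @inheritParams pruning_loglik
#' @return Tibble of class `rate_table` (`gene`, `species`, `root_to_tip`,
#'   `group`) with the per-gene fits in attribute `fits`.
#' @export
rate_table <- function(alignments, topology, outgroup, groups = NULL,
                       model = c("JC69", "K80"), kappa = 2) {
  model <- match.arg(model)
  fits <- list(); rows <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    keep <- intersect(topology$tip.label, aln$id)
    if (!outgroup %in% keep || length(keep) < 3) next
    tr <- ape::keep.tip(topology, keep)
    fit <- fit_branch_lengths(tr, aln[aln$id %in% keep, ], model, kappa)
    fits[[g]] <- fit
    for (sp in setdiff(keep, outgroup)) {
      rows[[paste(g, sp)]] <- tibble(
        gene = g, species = sp,
        root_to_tip = root_to_tip(fit$tree, sp, "ingroup", outgroup)
      )
    }
  }
  out <- bind_rows(rows)
  if (!is.null(groups)) {
    out <- left_join(out, as_tibble(groups), by = c("gene", "species"))
    out$group[is.na(out$group)] <- "outside_locus"
  } else {
    out$group <- "outside_locus"
  }
  attr(out, "fits") <- fits
  class(out) <- c("rate_table", class(out))
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transformed sample skewness and kurtosis into
#' \eqn{K^2 = z_s^2 + z_k^2}, referred to a chi-squared distribution with 2
#' degrees of freedom. Requires at least 8 observations.
#'
#' @param x numeric sample.
#' @return List of class `dagostino_test` with `statistic` (K2), `p.value`,
#'   `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) abort("the omnibus normality test needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_k <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z_s^2 + z_k^2
  structure(list(statistic = K2, p.value = pchisq(K2, 2, lower.tail = FALSE),
                 z_skew = z_s, z_kurt = z_k, n = n),
            class = "dagostino_test")
}

#' @export
print.dagostino_test <- function(x, ...) {
  cat(sprintf("<dagostino_test> K2 = %.4f, p = %.4g (n = %d)\n",
              x$statistic, x$p.value, x$n))
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Both samples are tested for normality with [dagostino_pearson()]; when
#' both pass at `alpha_norm` (which requires n >= 8 in each group, the
#' minimum for the omnibus test) an unpaired two-tailed equal-variance t-test
#' is used, otherwise a two-sided Mann-Whitney U test (exact when both n <=
#' 20 and there are no ties, normal approximation with tie correction
#' otherwise). Groups with fewer than 3 observations are rejected outright.
#'
#' @param g1,g2 numeric samples.
#' @param alpha_norm significance level of the normality gate.
#' @return Object of class `group_comparison`: `n1`, `n2`, `mean1`, `mean2`,
#'   `sem1`, `sem2`, `normality_p` (length 2), `test` ("t" or
#'   "mann_whitney"), `statistic`, `p.value`.
#' @export
compare_groups <- function(g1, g2, alpha_norm = 0.05) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  if (length(g1) < 3 || length(g2) < 3) {
    abort("fewer than 3 data points in a group: comparison excluded")
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  norm_p <- vapply(list(g1, g2), function(v) {
    if (length(v) < 8) NA_real_ else dagostino_pearson(v)$p.value
  }, numeric(1))
  use_t <- !anyNA(norm_p) && all(norm_p > alpha_norm)
  if (use_t) {
    ht <- t.test(g1, g2, var.equal = TRUE)
    test <- "t"
  } else {
    exact <- length(g1) <= 20 && length(g2) <= 20 &&
      !any(duplicated(c(g1, g2)))
    ht <- suppressWarnings(wilcox.test(g1, g2, exact = exact,
                                       correct = TRUE))
    test <- "mann_whitney"
  }
  structure(list(
    n1 = length(g1), n2 = length(g2),
    mean1 = mean(g1), mean2 = mean(g2),
    sem1 = sem(g1), sem2 = sem(g2),
    normality_p = norm_p, test = test,
    statistic = unname(ht$statistic), p.value = ht$p.value
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s test: statistic %.3f, p = %.4g\n",
              x$test, x$statistic, x$p.value))
  cat(sprintf("  group 1: n = %d, mean = %.4g (SEM %.3g)\n",
              x$n1, x$mean1, x$sem1))
  cat(sprintf("  group 2: n = %d, mean = %.4g (SEM %.3g)\n",
              x$n2, x$mean2, x$sem2))
  invisible(x)
}

#' Collapse a rate table and compare two groups
#'
#' Collapses the rate table to one value per gene and group (the mean
#' root-to-tip over the species carrying that group label, restricted to
#' `species` when given) so that group members are independent, then runs
#' [compare_groups()].
#'
#' @param rates a [rate_table()].
#' @param group1,group2 group labels to compare.
#' @param species optional species subset over which values are averaged.
#' @param alpha_norm normality gate level.
#' @return A `group_comparison`, with the collapsed per-gene values in
#'   attribute `values`.
#' @export
compare_rate_groups <- function(rates, group1 = "salvaged_locus",
                                group2 = "intact_locus", species = NULL,
                                alpha_norm = 0.05) {
  df <- as_tibble(rates)
  if (!is.null(species)) df <- filter(df, .data$species %in% !!species)
  per_gene <- df |>
    filter(.data$group %in% c(group1, group2)) |>
    group_by(.data$gene, .data$group) |>
    summarise(value = mean(.data$root_to_tip), .groups = "drop")
  v1 <- per_gene$value[per_gene$group == group1]
  v2 <- per_gene$value[per_gene$group == group2]
  out <- compare_groups(v1, v2, alpha_norm)
  attr(out, "values") <- per_gene
  out
}
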