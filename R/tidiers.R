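# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a branch-length fit
#'
#' One row per branch: parent and child node ids, the child node's label and
#' the fitted length.
#'
#' @param x a `branch_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.branch_fit <- function(x, ...) {
  tree <- x$tree
  tibble(
    parent = tree$edge[, 1],
    node = tree$edge[, 2],
    label = vapply(tree$edge[, 2], function(v) node_name(label_nodes(tree), v),
                   character(1)),
    branch_length = tree$edge.length
  )
}

#' @rdname tidy.branch_fit
#' @export
glance.branch_fit <- function(x, ...) {
  tibble(logLik = x$loglik, sweeps = x$sweeps, converged = x$converged,
         model = x$model, n_branches = length(x$tree$edge.length))
}

#' Tidy a two-group rate comparison
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return One-row tibble with the chosen test, statistic and p-value.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    test = x$test, statistic = x$statistic, p.value = x$p.value,
    n1 = x$n1, n2 = x$n2, mean1 = x$mean1, mean2 = x$mean2,
    sem1 = x$sem1, sem2 = x$sem2,
    normality_p1 = x$normality_p[1], normality_p2 = x$normality_p[2]
  )
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' Tidy a disruption report
#'
#' @param x a `disruption_report`.
#' @param ... unused.
#' @return The per-gene fate tibble with the species attached.
#' @export
tidy.disruption_report <- function(x, ...) {
  mutate(x$fates, species = x$species, .before = 1)
}

#' @rdname tidy.disruption_report
#' @export
glance.disruption_report <- function(x, ...) {
  tibble(
    species = x$species,
    n_blocks = nrow(x$blocks),
    n_inversions = nrow(x$inversions),
    breakpoints = x$breakpoints,
    n_lost = sum(x$fates$fate == "lost"),
    n_salvaged = sum(x$fates$fate == "salvaged"),
    n_retained = sum(x$fates$fate == "retained_in_locus"),
    disrupted_segment_genes = if (nrow(x$disrupted_segments) > 0)
      x$disrupted_segments$n_genes[1] else 0L
  )
}

#' Tidy an orthology verdict
#'
#' @param x an `ortholog_verdict`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
tidy.ortholog_verdict <- function(x, ...) {
  tibble(status = x$status, reason = x$reason, identity = x$identity,
         divergence = x$divergence, aligned_aa = x$aligned_aa,
         besthit_pass = x$besthit_pass)
}
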