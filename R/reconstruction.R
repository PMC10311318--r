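# From ancestral relation to consensus tree: collapse mutually-ancestral
# mutations into clone nodes, build the closure DAG, transitively reduce it,
# and verify the result is an arborescence.

#' Build the closure DAG of a relation solution
#'
#' Mutations `a`, `b` with `x_ab = x_ba = 1` label the same node (their
#' order is unresolved, so they form one clone). Nodes are the equivalence
#' classes of this mutual relation; there is an edge between two nodes when
#' any (equivalently, by transitivity and the single-lineage condition,
#' every) mutation of the first is ancestral to every mutation of the
#' second.
#'
#' @param sol A `relation_solution`.
#' @return A `closure_dag`: list with `labels` (list of mutation vectors,
#'   one per node) and `edges` (two-column integer matrix of node indices).
#' @export
relation_to_dag <- function(sol) {
  x <- sol$x
  muts <- sol$mutations
  m <- length(muts)
  mutual <- (x == 1L) & (t(x) == 1L)
  diag(mutual) <- TRUE
  # mutuality must be an equivalence relation for classes to be well defined
  comp <- rep(NA_integer_, m)
  k <- 0L
  for (a in seq_len(m)) {
    if (is.na(comp[a])) {
      k <- k + 1L
      members <- which(mutual[a, ])
      if (any(!is.na(comp[members])) ||
          !all(mutual[members, members]))
        mtt_error("mtt_invariant_error",
                  "mutual ancestral relation is not an equivalence relation")
      comp[members] <- k
    }
  }
  labels <- split(muts, factor(comp, levels = seq_len(k)))
  reps <- vapply(seq_len(k), function(i) which(comp == i)[1L], integer(1))
  edges <- matrix(integer(0), ncol = 2)
  for (v in seq_len(k)) for (w in seq_len(k)) {
    if (v != w && x[reps[v], reps[w]] == 1L) {
      # representative suffices, but verify all cross pairs agree
      if (!all(x[comp == v, comp == w] == 1L))
        mtt_error("mtt_invariant_error",
                  "ancestral relation not constant across node classes")
      edges <- rbind(edges, c(v, w))
    }
  }
  dag <- structure(list(labels = labels, edges = edges),
                   class = "closure_dag")
  if (dag_has_cycle(dag))
    mtt_error("mtt_invariant_error", "closure DAG contains a cycle")
  dag
}

dag_has_cycle <- function(dag) {
  k <- length(dag$labels)
  adj <- matrix(FALSE, k, k)
  if (nrow(dag$edges)) adj[dag$edges] <- TRUE
  indeg <- colSums(adj)
  queue <- which(indeg == 0L)
  removed <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    removed <- removed + 1L
    for (w in which(adj[v, ])) {
      adj[v, w] <- FALSE
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  removed < k
}

#' Transitive reduction of a closure DAG into an m-tumor tree
#'
#' The transitive reduction of a DAG is its unique minimal edge set
#' preserving reachability. For a closure DAG produced by the consensus
#' ILP the reduction is guaranteed to be an arborescence; this function
#' computes it, verifies that guarantee, and returns the corresponding
#' m-tumor tree.
#'
#' Because the input edge relation is transitively closed, an edge `(v, w)`
#' is redundant exactly when some intermediate node `u` has edges
#' `(v, u)` and `(u, w)`.
#'
#' @param dag A `closure_dag` from [relation_to_dag()].
#' @return An `mtumor_tree`.
#' @export
transitive_reduction <- function(dag) {
  k <- length(dag$labels)
  adj <- matrix(FALSE, k, k)
  if (nrow(dag$edges)) adj[dag$edges] <- TRUE
  redundant <- (adj %*% adj) > 0  # two-step reachability within the closure
  reduced <- adj & !redundant
  parent <- rep(NA_character_, k)
  ids <- paste0("n", seq_len(k))
  for (w in seq_len(k)) {
    ps <- which(reduced[, w])
    if (length(ps) > 1L)
      mtt_error("mtt_invariant_error",
                "transitive reduction is not an arborescence: node with two parents")
    if (length(ps) == 1L) parent[w] <- ids[ps]
  }
  if (sum(is.na(parent)) != 1L)
    mtt_error("mtt_invariant_error",
              "transitive reduction is not an arborescence: multiple roots")
  names(parent) <- ids
  labels <- dag$labels
  names(labels) <- ids
  tree <- mtumor_tree(parent, labels)  # validation checks reachability
  tree
}

#' Check the arborescence property
#'
#' `TRUE` when the directed graph given by a parent map has exactly one
#' root and every node is reachable from it by exactly one path.
#'
#' @param parent Named character vector mapping node to parent (`NA` at the
#'   root), or an `mtumor_tree` (whose parent map is used).
#' @return `TRUE` or `FALSE`; never errors.
#' @export
is_arborescence <- function(parent) {
  if (inherits(parent, "mtumor_tree")) parent <- parent$parent
  nodes <- names(parent)
  if (!length(nodes) || anyDuplicated(nodes)) return(FALSE)
  roots <- nodes[is.na(parent)]
  if (length(roots) != 1L) return(FALSE)
  if (any(!stats::na.omit(parent) %in% nodes)) return(FALSE)
  # a parent map gives each node at most one in-edge, so it only remains to
  # check that every node reaches the root without cycling
  for (v in nodes) {
    seen <- character(0)
    while (!is.na(parent[[v]])) {
      if (v %in% seen) return(FALSE)
      seen <- c(seen, v)
      v <- parent[[v]]
    }
  }
  TRUE
}

solution_to_tree <- function(sol) {
  tree <- transitive_reduction(relation_to_dag(sol))
  # closure round-trip: the tree's AD relation must reproduce x exactly
  if (!identical(pairs_to_relation(ad_pairs(tree), sol$mutations),
                 sol$x))
    mtt_error("mtt_invariant_error",
              "reconstructed tree does not reproduce the solved relation")
  # root indicators must point at the root node's mutations
  root_muts <- sort(tree$labels[[root_node(tree)]])
  if (!identical(sort(names(sol$r)[sol$r == 1L]), root_muts))
    mtt_error("mtt_invariant_error",
              "root indicators disagree with the reconstructed root")
  tree
}

#' Weighted consensus of m-tumor trees
#'
#' Solves the weighted consensus problem under AD distance: finds the
#' m-tumor tree (or, with `all_optima = TRUE`, every m-tumor tree up to
#' `limit`) minimizing the total weighted ancestor-descendant distance to
#' the input trees, via the ancestral-relation ILP followed by transitive
#' reduction.
#'
#' With `harmonize = TRUE` the inputs may be over different mutation sets:
#' the consensus is taken over the mutations present in strictly more than
#' half of the input trees, and each input contributes the restriction of
#' its ancestral relation to that set.
#'
#' @param trees List of `mtumor_tree` objects, or a [weighted_instance()].
#' @param weights Confidence weights, one per tree (`NULL` = equal). Must
#'   be nonnegative and sum to 1 unless `normalize = TRUE`.
#' @param all_optima Enumerate every co-optimal consensus tree.
#' @param limit Cap on the number of optima returned.
#' @param harmonize Apply the majority rule to inputs over different
#'   mutation sets.
#' @param normalize Rescale weights to sum to 1.
#' @param time_limit Solver wall-clock limit in seconds.
#' @return A `consensus_result`: list with `trees` (canonically ordered
#'   list of `mtumor_tree`), `objective` (minimum total weighted AD
#'   distance), and `truncated`.
#' @examples
#' \dontrun{
#' t1 <- parse_tree("1\t-\tA\n2\t1\tB\n3\t2\tC")
#' t2 <- parse_tree("1\t-\tA\n2\t1\tC\n3\t2\tB")
#' consensus(list(t1, t2), weights = c(0.7, 0.3))
#' }
#' @export
consensus <- function(trees, weights = NULL, all_optima = FALSE,
                      limit = 100L, harmonize = FALSE, normalize = FALSE,
                      time_limit = 600) {
  if (inherits(trees, "weighted_instance")) {
    sm <- support_matrix(trees)
  } else if (harmonize) {
    sm <- harmonized_support(trees, weights, normalize = normalize)
  } else {
    sm <- support_matrix(weighted_instance(trees, weights,
                                           normalize = normalize))
  }
  model <- build_model(sm)
  if (all_optima) {
    res <- enumerate_optima(model, limit = limit, time_limit = time_limit)
    sols <- res$solutions
    truncated <- res$truncated
  } else {
    sols <- list(solve_model(model, time_limit = time_limit))
    truncated <- FALSE
  }
  out_trees <- lapply(sols, solution_to_tree)
  ord <- order(vapply(out_trees, write_tree, character(1)))
  structure(list(trees = out_trees[ord],
                 objective = sols[[1L]]$objective_value,
                 truncated = truncated),
            class = "consensus_result")
}

#' Batch consensus over many instances
#'
#' Solves one consensus problem per instance in a single solver-worker
#' invocation, amortizing startup cost across e.g. the trials of a
#' simulation study.
#'
#' @param instances List of [weighted_instance()] objects.
#' @param all_optima Enumerate every co-optimal tree per instance.
#' @param limit Per-instance cap on enumerated optima.
#' @param time_limit Solver wall-clock limit in seconds, per instance.
#' @return List of `consensus_result` objects.
#' @export
consensus_batch <- function(instances, all_optima = FALSE, limit = 100L,
                            time_limit = 600) {
  models <- lapply(instances, build_model)
  live <- !vapply(models, function(mo) isTRUE(mo$trivial), logical(1))
  results <- vector("list", length(models))
  if (any(live)) {
    probs <- lapply(models[live], model_problem,
                    limit = if (all_optima) as.integer(limit) else 1L,
                    probe = all_optima)
    res <- milp_solve_batch(probs, time_limit = time_limit)
    results[live] <- Map(function(mo, r) solutions_from_result(mo, r),
                         models[live], res)
  }
  results[!live] <- lapply(models[!live], function(mo)
    list(solutions = list(trivial_solution(mo)), truncated = FALSE))
  lapply(results, function(res) {
    out_trees <- lapply(res$solutions, solution_to_tree)
    ord <- order(vapply(out_trees, write_tree, character(1)))
    structure(list(trees = out_trees[ord],
                   objective = res$solutions[[1L]]$objective_value,
                   truncated = res$truncated),
              class = "consensus_result")
  })
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus: ", length(x$trees), " optimal tree(s), ",
      "total weighted AD distance ", format(x$objective), "\n", sep = "")
  if (x$truncated) cat("(enumeration truncated: more optima exist)\n")
  for (t in x$trees) cat(write_tree(t), "\n", sep = "")
  invisible(x)
}
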