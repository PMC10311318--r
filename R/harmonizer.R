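# Majority-rule harmonization of input trees over different mutation sets.

#' Majority-rule mutation set
#'
#' A mutation enters the consensus only when it occurs in strictly more
#' than half of the input trees.
#'
#' @param trees List of `mtumor_tree` objects (mutation sets may differ).
#' @return Sorted character vector of retained mutations.
#' @export
majority_mutations <- function(trees) {
  if (!length(trees)) mtt_error("mtt_instance_error", "need at least one tree")
  counts <- table(unlist(lapply(trees, function(t) t$mutations)))
  keep <- names(counts)[counts > length(trees) / 2]
  if (!length(keep))
    mtt_error("mtt_harmonize_error",
              "no mutation occurs in more than half of the input trees")
  sort(keep)
}

#' Restrict a tree's ancestor-descendant relation to a mutation subset
#'
#' Unlike [restrict_tree()] this is always well defined, even when the
#' restriction of the tree is a forest: it simply intersects the AD pair
#' set with `keep x keep`. Harmonized consensus consumes these restricted
#' relations directly.
#'
#' @param tree An `mtumor_tree`.
#' @param keep Character vector of mutations to retain.
#' @return A `mutation_pairs` vector.
#' @export
restrict_ad_pairs <- function(tree, keep) {
  p <- pairs_to_matrix(ad_pairs(tree))
  sel <- p[, 1] %in% keep & p[, 2] %in% keep
  structure(sort(pair_key(p[sel, 1], p[sel, 2])), class = "mutation_pairs")
}

#' Restrict an m-tumor tree to a subset of its mutations
#'
#' Deletes mutations outside `keep` and contracts nodes whose labels become
#' empty, so that ancestral relations among the kept mutations are
#' preserved exactly: the restricted tree's AD pairs are the original
#' tree's AD pairs intersected with `keep x keep`.
#'
#' When the entire root label is deleted and its surviving descendants are
#' not nested under a single lineage, the restricted relation is a forest
#' and no valid single-rooted m-tumor tree exists; an error of class
#' `mtt_forest_error` is raised. Harmonized consensus does not need a tree
#' per input in that case: it consumes the restricted pair relation
#' directly (see [consensus()] with `harmonize = TRUE`).
#'
#' @param tree An `mtumor_tree`.
#' @param keep Character vector of mutations to retain.
#' @return An `mtumor_tree` over `intersect(keep, tree$mutations)`.
#' @export
restrict_tree <- function(tree, keep) {
  kept <- intersect(tree$mutations, keep)
  if (!length(kept))
    mtt_error("mtt_harmonize_error",
              "restriction would remove every mutation in the tree")
  pairs <- restrict_ad_pairs(tree, kept)
  x <- pairs_to_relation(pairs, sort(kept))
  # reuse the closure machinery: the restricted relation is transitively
  # closed and single-lineage, so reduction applies directly
  sol <- structure(list(mutations = sort(kept), x = x,
                        r = as.integer(rowSums(x) == length(kept) - 1L)),
                   class = "relation_solution")
  dag <- relation_to_dag(sol)
  tryCatch(transitive_reduction(dag),
           mtt_invariant_error = function(e)
             mtt_error("mtt_forest_error",
                       paste0("restriction yields a forest (the whole root ",
                              "label was removed); use harmonized consensus, ",
                              "which operates on restricted ancestral pair ",
                              "relations directly")))
}

# support matrix for harmonized consensus: majority mutation set, each
# input contributing its restricted AD relation (valid even when the
# restriction is a forest, since only the pair indicators enter the ILP)
harmonized_support <- function(trees, weights = NULL, normalize = FALSE) {
  if (is.null(weights)) weights <- rep(1 / length(trees), length(trees))
  if (length(weights) != length(trees))
    mtt_error("mtt_instance_error", "one weight per tree required")
  if (any(weights < 0))
    mtt_error("mtt_instance_error", "weights must be nonnegative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    if (normalize && s > 0) weights <- weights / s
    else mtt_error("mtt_instance_error", "weights must sum to 1")
  }
  keep <- majority_mutations(trees)
  pair_sets <- lapply(trees, restrict_ad_pairs, keep = keep)
  support_from_pairs(pair_sets, weights, keep)
}
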