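# Tree distance measures over ancestral and parent-child mutation pairs.

check_same_mutations <- function(t1, t2) {
  if (!identical(t1$mutations, t2$mutations))
    mtt_error("mtt_mutation_set_error",
              paste0("trees are over different mutation sets; harmonize ",
                     "them first (see majority_mutations / restrict_tree)"))
}

#' Ancestor-descendant distance between two m-tumor trees
#'
#' The AD distance is the size of the symmetric difference of the two
#' trees' ancestor-descendant pair sets: the number of ordered mutation
#' pairs `(a, b)` with `a` ancestral to `b` in one tree but not the other.
#' It is a metric on m-tumor trees over a fixed mutation set.
#'
#' @param t1,t2 `mtumor_tree` objects over the same mutation set.
#' @return Nonnegative integer.
#' @examples
#' a <- parse_tree("1\t-\tA\n2\t1\tB\n3\t2\tC")
#' b <- parse_tree("1\t-\tA\n2\t1\tC\n3\t2\tB")
#' ad_distance(a, b)  # 2
#' @export
ad_distance <- function(t1, t2) {
  check_same_mutations(t1, t2)
  p1 <- unclass(ad_pairs(t1)); p2 <- unclass(ad_pairs(t2))
  length(setdiff(p1, p2)) + length(setdiff(p2, p1))
}

#' Parent-child distance between two m-tumor trees
#'
#' Counts the parent-child mutation pairs present in exactly one of the two
#' trees. Shorter-ranged than [ad_distance()]: it only registers direct
#' parental relationships, not longer ancestral chains.
#'
#' @inheritParams ad_distance
#' @return Nonnegative integer.
#' @export
pc_distance <- function(t1, t2) {
  check_same_mutations(t1, t2)
  p1 <- unclass(pc_pairs(t1)); p2 <- unclass(pc_pairs(t2))
  length(setdiff(p1, p2)) + length(setdiff(p2, p1))
}

resolve_metric <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(match.arg(metric, c("ad", "pc")),
         ad = ad_distance, pc = pc_distance)
}

#' Weighted instance of the consensus problem
#'
#' Bundles the input trees and their confidence weights. Weights must be
#' nonnegative and sum to 1 (within 1e-9); `normalize = TRUE` rescales
#' arbitrary nonnegative weights to sum to 1.
#'
#' @param trees List of `mtumor_tree` objects over a common mutation set.
#' @param weights Numeric vector, one weight per tree; `NULL` for equal
#'   weights `1/n`.
#' @param normalize Rescale weights to sum to 1 instead of erroring.
#' @return An object of class `weighted_instance`.
#' @export
weighted_instance <- function(trees, weights = NULL, normalize = FALSE) {
  if (!length(trees)) mtt_error("mtt_instance_error", "need at least one tree")
  if (is.null(weights)) weights <- rep(1 / length(trees), length(trees))
  if (length(weights) != length(trees))
    mtt_error("mtt_instance_error", "one weight per tree required")
  if (any(weights < 0))
    mtt_error("mtt_instance_error", "weights must be nonnegative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    if (normalize && s > 0) weights <- weights / s
    else mtt_error("mtt_instance_error",
                   paste0("weights sum to ", format(s),
                          ", not 1 (use normalize = TRUE to rescale)"))
  }
  muts <- trees[[1L]]$mutations
  for (t in trees[-1L]) {
    if (!identical(t$mutations, muts))
      mtt_error("mtt_mutation_set_error",
                "input trees are over different mutation sets; harmonize first")
  }
  structure(list(trees = trees, weights = weights, mutations = muts),
            class = "weighted_instance")
}

#' Total weighted distance from a candidate tree to an instance
#'
#' Computes `sum_i w_i * dist(candidate, T_i)`, the objective of the
#' weighted consensus problem.
#'
#' @param candidate An `mtumor_tree` over the instance's mutation set.
#' @param instance A [weighted_instance()].
#' @param metric `"ad"`, `"pc"`, or a distance function of two trees.
#' @return Nonnegative real.
#' @export
weighted_total_distance <- function(candidate, instance, metric = "ad") {
  stopifnot(inherits(instance, "weighted_instance"))
  dist_fn <- resolve_metric(metric)
  d <- vapply(instance$trees, function(t) dist_fn(candidate, t), numeric(1))
  sum(instance$weights * d)
}
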