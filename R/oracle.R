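# Brute-force enumeration of the m-tumor tree space and exhaustive
# consensus search. Exists as an independent correctness check for the ILP
# on small mutation sets; the combinatorics (Bell numbers times rooted
# labeled trees) forbid anything beyond m ~ 5.

# all set partitions of a character vector, via restricted growth strings
set_partitions <- function(items) {
  n <- length(items)
  out <- list()
  recurse <- function(i, assignment, nblocks) {
    if (i > n) {
      blocks <- split(items, factor(assignment, levels = seq_len(nblocks)))
      out[[length(out) + 1L]] <<- unname(blocks)
      return(invisible())
    }
    for (b in seq_len(nblocks + 1L)) {
      assignment[i] <- b
      recurse(i + 1L, assignment, max(nblocks, b))
    }
  }
  recurse(1L, integer(n), 0L)
  out
}

# all rooted labeled trees on k nodes as parent vectors (0 = root)
rooted_parent_vectors <- function(k) {
  if (k == 1L) return(list(0L))
  out <- list()
  for (root in seq_len(k)) {
    others <- setdiff(seq_len(k), root)
    # mixed-radix enumeration of parent choices for non-root nodes
    counter <- rep(1L, k - 1L)
    repeat {
      parent <- integer(k)
      parent[others] <- counter
      parent[root] <- 0L
      # validity: every node reaches the root (no cycles off the root)
      ok <- TRUE
      for (v in others) {
        seen <- integer(0)
        u <- v
        while (u != root) {
          if (u %in% seen) { ok <- FALSE; break }
          seen <- c(seen, u)
          u <- parent[u]
        }
        if (!ok) break
      }
      if (ok) out[[length(out) + 1L]] <- parent
      # increment counter
      pos <- 1L
      while (pos <= k - 1L) {
        counter[pos] <- counter[pos] + 1L
        if (counter[pos] <= k) break
        counter[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > k - 1L) break
    }
  }
  out
}

#' Enumerate every m-tumor tree over a mutation set
#'
#' Crosses every set partition of the mutations (the mutation clustering)
#' with every rooted labeled tree on the partition's blocks. Each m-tumor
#' tree is produced exactly once up to isomorphism.
#'
#' @param mutations Character vector of mutation identifiers, `|mutations|`
#'   at most `cap`.
#' @param cap Safety cap on the mutation count (default 5; the space has
#'   1521 trees at m = 5 and grows super-exponentially).
#' @return List of `mtumor_tree` objects.
#' @export
enumerate_m_tumor_trees <- function(mutations, cap = 5L) {
  m <- length(mutations)
  if (m > cap)
    mtt_error("mtt_oracle_error",
              paste0("enumeration of ", m, "-mutation trees exceeds the cap (",
                     cap, "); the tree space grows as Bell(m) * k^(k-1)"))
  if (m == 0L) mtt_error("mtt_oracle_error", "empty mutation set")
  out <- list()
  for (blocks in set_partitions(mutations)) {
    k <- length(blocks)
    ids <- paste0("n", seq_len(k))
    for (parent_vec in rooted_parent_vectors(k)) {
      parent <- rep(NA_character_, k)
      nonroot <- parent_vec > 0L
      parent[nonroot] <- ids[parent_vec[nonroot]]
      names(parent) <- ids
      labels <- blocks
      names(labels) <- ids
      out[[length(out) + 1L]] <- mtumor_tree(parent, labels,
                                             validate = FALSE)
    }
  }
  out
}

#' Exhaustive consensus search (independent oracle)
#'
#' Evaluates the total weighted distance of every m-tumor tree over the
#' instance's mutation set and returns the exact minimum together with all
#' trees achieving it. Used to validate the ILP on small instances.
#'
#' @param instance A [weighted_instance()].
#' @param metric `"ad"`, `"pc"`, or a distance function.
#' @param cap Mutation-count cap passed to [enumerate_m_tumor_trees()].
#' @return List with `objective` (the minimum) and `trees` (all optimal
#'   trees, in canonical-serialization order).
#' @export
brute_force_consensus <- function(instance, metric = "ad", cap = 5L) {
  stopifnot(inherits(instance, "weighted_instance"))
  candidates <- enumerate_m_tumor_trees(instance$mutations, cap = cap)
  objs <- vapply(candidates, weighted_total_distance, numeric(1),
                 instance = instance, metric = metric)
  best <- min(objs)
  opt <- candidates[objs <= best + 1e-9]
  ord <- order(vapply(opt, write_tree, character(1)))
  list(objective = best, trees = opt[ord])
}
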