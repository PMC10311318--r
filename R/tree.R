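# Core m-tumor tree data model: construction, validation, text serialization,
# canonical form, and ancestral / parent-child pair extraction.

PAIR_SEP <- "\x1f"

mtt_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mtt_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Construct an m-tumor tree
#'
#' An m-tumor tree is a rooted directed tree whose nodes are labelled by
#' disjoint, nonempty sets of mutation identifiers that together partition
#' the tree's mutation set. Nodes represent clones; an edge points from a
#' parent clone to a child clone that descends from it.
#'
#' @param parent Named character vector mapping each node id to its parent
#'   node id; the root's entry is `NA`.
#' @param labels Named list mapping each node id to a nonempty character
#'   vector of mutation identifiers. Identifiers are arbitrary strings but
#'   may not contain tabs, commas, or control characters.
#' @param validate Check all structural invariants (default `TRUE`).
#' @return An object of class `mtumor_tree` with fields `nodes`, `parent`,
#'   `labels` and `mutations` (the sorted union of all labels).
#' @examples
#' t <- mtumor_tree(parent = c(n1 = NA, n2 = "n1"),
#'                  labels = list(n1 = "A", n2 = c("B", "C")))
#' ad_pairs(t)
#' @export
mtumor_tree <- function(parent, labels, validate = TRUE) {
  nodes <- names(parent)
  labels <- lapply(labels, as.character)
  tree <- structure(
    list(nodes = nodes,
         parent = parent,
         labels = labels[nodes],
         mutations = sort(unique(unlist(labels, use.names = FALSE)))),
    class = "mtumor_tree")
  if (validate) validate_mtumor_tree(tree)
  tree
}

#' Validate m-tumor tree invariants
#'
#' Checks that the labels partition the mutation set (disjoint, nonempty)
#' and that the parent map induces a single rooted tree (one root, no
#' cycles, all nodes reachable from the root).
#'
#' @param tree An `mtumor_tree`.
#' @return The tree, invisibly; errors on the first violated invariant.
#' @export
validate_mtumor_tree <- function(tree) {
  nodes <- tree$nodes
  if (length(nodes) == 0L)
    mtt_error("mtt_validation_error", "tree has no nodes")
  if (anyDuplicated(nodes))
    mtt_error("mtt_validation_error", "duplicate node ids")
  if (!identical(sort(names(tree$labels)), sort(nodes)))
    mtt_error("mtt_validation_error", "labels must be named by node id")
  lens <- lengths(tree$labels)
  if (any(lens == 0L))
    mtt_error("mtt_validation_error",
              paste0("empty mutation label at node ",
                     nodes[which(lens == 0L)[1L]]))
  muts <- unlist(tree$labels, use.names = FALSE)
  if (anyDuplicated(muts)) {
    dup <- muts[duplicated(muts)][1L]
    mtt_error("mtt_validation_error",
              paste0("mutation ", dup, " labels more than one node"))
  }
  roots <- nodes[is.na(tree$parent[nodes])]
  if (length(roots) != 1L)
    mtt_error("mtt_validation_error",
              paste0(length(roots), " root nodes found; need exactly 1"))
  bad <- setdiff(stats::na.omit(tree$parent), nodes)
  if (length(bad))
    mtt_error("mtt_validation_error",
              paste0("unknown parent node id: ", bad[1L]))
  # reachability from root detects cycles and disconnected parts
  kids <- children_map(tree)
  seen <- character(0)
  queue <- roots
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- c(seen, v)
    queue <- c(queue, kids[[v]])
  }
  if (length(seen) != length(nodes))
    mtt_error("mtt_validation_error",
              "parent map contains a cycle or disconnected component")
  invisible(tree)
}

children_map <- function(tree) {
  kids <- lapply(tree$nodes, function(v) character(0))
  names(kids) <- tree$nodes
  for (v in tree$nodes) {
    p <- tree$parent[[v]]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

root_node <- function(tree) tree$nodes[is.na(tree$parent[tree$nodes])]

# breadth-first node order with children sorted by smallest label member
bfs_order <- function(tree) {
  kids <- children_map(tree)
  key <- vapply(tree$labels, function(l) min(l), character(1))
  order <- character(0)
  queue <- root_node(tree)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    ch <- kids[[v]]
    if (length(ch)) queue <- c(queue, ch[order(key[ch])])
  }
  order
}

#' Parse an m-tumor tree from its text representation
#'
#' The format is one node per line:
#' `node_id<TAB>parent_id<TAB>mut1,mut2,...`, with `-` as the parent of the
#' root. Anything after `#` is a comment; blank lines are ignored.
#'
#' @param text A single string, or a character vector of lines.
#' @return A validated [mtumor_tree()].
#' @seealso [write_tree()], [read_tree_file()]
#' @export
parse_tree <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  parent <- character(0)
  labels <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 3L)
      mtt_error("mtt_parse_error",
                paste0("line ", i, ": expected 3 tab-separated fields, got ",
                       length(fields)))
    id <- trimws(fields[1L]); pid <- trimws(fields[2L])
    muts <- trimws(strsplit(fields[3L], ",", fixed = TRUE)[[1L]])
    muts <- muts[nzchar(muts)]
    if (!nzchar(id))
      mtt_error("mtt_parse_error", paste0("line ", i, ": empty node id"))
    if (id %in% names(parent))
      mtt_error("mtt_parse_error", paste0("line ", i, ": duplicate node id ", id))
    if (!length(muts))
      mtt_error("mtt_parse_error", paste0("line ", i, ": empty mutation label"))
    parent[[id]] <- if (pid == "-") NA_character_ else pid
    labels[[id]] <- muts
  }
  if (!length(parent)) mtt_error("mtt_parse_error", "no nodes found")
  mtumor_tree(parent, labels)
}

#' Read an m-tumor tree from a file
#' @param path Path to a tree text file.
#' @return A validated [mtumor_tree()].
#' @export
read_tree_file <- function(path) parse_tree(readLines(path, warn = FALSE))

#' Serialize an m-tumor tree to its canonical text form
#'
#' Nodes are renumbered 1..k in breadth-first order from the root, with
#' sibling order determined by the lexicographically smallest mutation in
#' each label, and mutations within a label sorted. Two trees are isomorphic
#' (same label partition and same parent relation on labels) if and only if
#' their serializations are byte-identical.
#'
#' @param tree An `mtumor_tree`.
#' @return A single string, one node per line, LF-terminated.
#' @export
write_tree <- function(tree) {
  ord <- bfs_order(tree)
  newid <- seq_along(ord)
  names(newid) <- ord
  lines <- vapply(ord, function(v) {
    p <- tree$parent[[v]]
    paste(newid[[v]],
          if (is.na(p)) "-" else newid[[p]],
          paste(sort(tree$labels[[v]]), collapse = ","),
          sep = "\t")
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write an m-tumor tree to a file
#' @param tree An `mtumor_tree`.
#' @param path Output file path.
#' @export
write_tree_file <- function(tree, path) {
  writeLines(sub("\n$", "", write_tree(tree)), path)
  invisible(path)
}

#' Test two m-tumor trees for isomorphism
#'
#' Equality is label-partition plus parent-relation isomorphism; node ids
#' are arbitrary and ignored.
#' @param t1,t2 `mtumor_tree` objects.
#' @return `TRUE` or `FALSE`.
#' @export
trees_equal <- function(t1, t2) identical(write_tree(t1), write_tree(t2))

#' @export
print.mtumor_tree <- function(x, ...) {
  cat("m-tumor tree:", length(x$nodes), "nodes,",
      length(x$mutations), "mutations\n")
  cat(write_tree(x))
  invisible(x)
}

pair_key <- function(a, b) paste(a, b, sep = PAIR_SEP)

pair_unkey <- function(keys) {
  if (!length(keys)) return(matrix(character(0), ncol = 2))
  do.call(rbind, strsplit(keys, PAIR_SEP, fixed = TRUE))
}

# all ordered pairs between two mutation vectors, excluding self-pairs
cross_pairs <- function(from, to) {
  if (!length(from) || !length(to)) return(character(0))
  g <- expand.grid(a = from, b = to, stringsAsFactors = FALSE)
  g <- g[g$a != g$b, , drop = FALSE]
  pair_key(g$a, g$b)
}

#' Ancestor-descendant pairs of a tree
#'
#' Mutation `a` is ancestral to `b` when `a` labels a node on the path from
#' the root to the node labelled by `b`. Mutations sharing a node are
#' mutually ancestral (their relative order within the clone is unknown),
#' so same-node pairs appear in both directions. Self-pairs are excluded.
#'
#' @param tree An `mtumor_tree`.
#' @return Sorted character vector of pair keys of class `mutation_pairs`;
#'   use [pairs_to_matrix()] for a two-column matrix view.
#' @export
ad_pairs <- function(tree) {
  ord <- bfs_order(tree)
  anc <- list()  # strict-ancestor mutation sets per node
  out <- character(0)
  for (v in ord) {
    p <- tree$parent[[v]]
    anc[[v]] <- if (is.na(p)) character(0) else c(anc[[p]], tree$labels[[p]])
    lab <- tree$labels[[v]]
    out <- c(out, cross_pairs(anc[[v]], lab), cross_pairs(lab, lab))
  }
  structure(sort(out), class = "mutation_pairs")
}

#' Parent-child pairs of a tree
#'
#' Mutation pair `(a, b)` is a parent-child pair when `a` labels the parent
#' of the node labelled by `b`. Mutations sharing a node are treated as
#' mutual parent-child pairs, mirroring the ancestor-descendant convention
#' for co-clustered mutations.
#'
#' @param tree An `mtumor_tree`.
#' @return Sorted character vector of pair keys of class `mutation_pairs`.
#' @export
pc_pairs <- function(tree) {
  out <- character(0)
  for (v in tree$nodes) {
    lab <- tree$labels[[v]]
    p <- tree$parent[[v]]
    out <- c(out, cross_pairs(lab, lab))
    if (!is.na(p)) out <- c(out, cross_pairs(tree$labels[[p]], lab))
  }
  structure(sort(unique(out)), class = "mutation_pairs")
}

#' Convert pair keys to a two-column character matrix
#' @param pairs A `mutation_pairs` vector (or plain key vector).
#' @return Character matrix with columns `ancestor`, `descendant`.
#' @export
pairs_to_matrix <- function(pairs) {
  m <- pair_unkey(unclass(pairs))
  colnames(m) <- c("ancestor", "descendant")
  m
}

#' @export
print.mutation_pairs <- function(x, ...) {
  m <- pairs_to_matrix(x)
  cat(length(x), "ordered mutation pairs\n")
  if (length(x)) print(paste0("(", m[, 1], " -> ", m[, 2], ")"))
  invisible(x)
}

# indicator matrix (m x m, 0 diagonal) of a pair-key set over `mutations`
pairs_to_relation <- function(pairs, mutations) {
  m <- length(mutations)
  x <- matrix(0L, m, m, dimnames = list(mutations, mutations))
  if (length(pairs)) {
    pm <- pair_unkey(unclass(pairs))
    x[pm] <- 1L
  }
  x
}

relation_to_pairs <- function(x) {
  idx <- which(x == 1L, arr.ind = TRUE)
  muts <- rownames(x)
  structure(sort(pair_key(muts[idx[, 1]], muts[idx[, 2]])),
            class = "mutation_pairs")
}
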