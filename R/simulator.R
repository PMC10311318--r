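# Clonal-tree simulator: ground-truth m-tumor trees with sum-rule-consistent
# mutation frequencies, and noisy input trees derived from the truth by
# subtree moves, frequency-guided edge collapses, and node expansions.

#' Simulation configuration
#'
#' @param m Number of mutations per tree.
#' @param n_trees Number of perturbed input trees per trial.
#' @param n_trials Number of trials in a dataset.
#' @param seed Integer seed for reproducibility (`NULL` = current RNG state).
#' @param move_prob Probability of moving each node's subtree to a
#'   grandparent or sibling during input-tree generation.
#' @param expand_prob Probability of splitting a multi-mutation node into a
#'   parent/child pair.
#' @param collapse Apply frequency-guided edge collapses (probability
#'   `freq(child)/freq(parent)`, higher for clones with similar
#'   frequencies, which are harder to distinguish in real data).
#' @param max_children_truth Branching cap for ground-truth trees.
#' @param max_children_input Branching cap enforced on perturbed trees.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(m, n_trees, n_trials = 1L, seed = NULL,
                              move_prob = 1 / 3, expand_prob = 1 / 3,
                              collapse = TRUE,
                              max_children_truth = 3L,
                              max_children_input = 4L) {
  stopifnot(m >= 1L, n_trees >= 1L, n_trials >= 1L,
            move_prob >= 0, move_prob <= 1,
            expand_prob >= 0, expand_prob <= 1,
            max_children_truth <= max_children_input)
  structure(list(m = as.integer(m), n_trees = as.integer(n_trees),
                 n_trials = as.integer(n_trials), seed = seed,
                 move_prob = move_prob, expand_prob = expand_prob,
                 collapse = collapse,
                 max_children_truth = as.integer(max_children_truth),
                 max_children_input = as.integer(max_children_input)),
            class = "simulation_config")
}

default_mutations <- function(m) sprintf("M%02d", seq_len(m))

#' Random mutation clustering
#'
#' Partitions `m` mutations into clusters so that the expected cluster
#' count is `1 + 0.75 (m - 1)`: after the first mutation opens the first
#' cluster, each subsequent mutation opens a new cluster with probability
#' 3/4 and otherwise joins a uniformly chosen existing one.
#'
#' @param m Number of mutations.
#' @param mutations Optional identifiers (default `M01..Mm`).
#' @return List of character vectors partitioning the mutations.
#' @export
random_clustering <- function(m, mutations = default_mutations(m)) {
  stopifnot(m >= 1L, length(mutations) == m)
  blocks <- list(mutations[1L])
  if (m > 1L) for (i in 2L:m) {
    if (stats::runif(1) < 0.75) {
      blocks[[length(blocks) + 1L]] <- mutations[i]
    } else {
      b <- sample.int(length(blocks), 1L)
      blocks[[b]] <- c(blocks[[b]], mutations[i])
    }
  }
  blocks
}

# internal mutable clone-tree state used during simulation
state_children <- function(state, v) names(state$parent)[
  !is.na(state$parent) & state$parent == v]

state_to_tree <- function(state) mtumor_tree(state$parent, state$labels)

#' Generate a ground-truth clone tree with frequencies
#'
#' Clusters the mutations ([random_clustering()]), attaches clusters in
#' random order to uniformly chosen existing nodes with fewer than
#' `max_children_truth` children, and assigns cellular frequencies top-down:
#' the root clone has frequency 1 and each clone's children receive a
#' symmetric Dirichlet(1) share of the parent's frequency with one retained
#' share, so the sum rule (a clone's frequency is at least the sum of its
#' children's) holds by construction.
#'
#' @param m Number of mutations.
#' @param config A [simulation_config()].
#' @return List with `tree` (an `mtumor_tree`) and `freq` (named numeric,
#'   one frequency per node in `(0, 1]`).
#' @export
random_true_tree <- function(m, config = simulation_config(m, 1L)) {
  blocks <- random_clustering(m)
  k <- length(blocks)
  ord <- if (k > 1L) sample.int(k) else 1L
  ids <- paste0("n", seq_len(k))
  parent <- stats::setNames(rep(NA_character_, k), ids)
  nchild <- stats::setNames(integer(k), ids)
  for (j in seq_along(ord)[-1L]) {
    repeat {
      p <- ids[ord[sample.int(j - 1L, 1L)]]
      if (nchild[[p]] < config$max_children_truth) break
    }
    parent[[ids[ord[j]]]] <- p
    nchild[[p]] <- nchild[[p]] + 1L
  }
  labels <- stats::setNames(blocks, ids)
  tree <- mtumor_tree(parent, labels)
  # top-down Dirichlet frequency assignment
  freq <- stats::setNames(numeric(k), ids)
  root <- root_node(tree)
  freq[[root]] <- 1
  kids <- children_map(tree)
  for (v in bfs_order(tree)) {
    ch <- kids[[v]]
    if (length(ch)) {
      shares <- stats::rexp(length(ch) + 1L)
      shares <- shares / sum(shares)
      freq[ch] <- freq[[v]] * shares[seq_along(ch)]
    }
  }
  list(tree = tree, freq = freq)
}

# one perturbation pass set over a copy of the truth state
#' Perturb a ground-truth tree into one noisy input tree
#'
#' Applies, in breadth-first order over the nodes present at the start of
#' each pass: (i) subtree moves to a grandparent or sibling with
#' probability `move_prob`; (ii) edge collapses with probability
#' `freq(child)/freq(parent)` (clones with near-identical frequencies are
#' the ones real inference methods merge); (iii) expansion of
#' multi-mutation nodes into a parent/child split with probability
#' `expand_prob`. Every modification is accepted only if the sum rule
#' still holds and no node exceeds `max_children_input` children; a
#' rejected move is re-drawn up to 10 times, then skipped.
#'
#' @param truth List with `tree` and `freq` as from [random_true_tree()].
#' @param config A [simulation_config()].
#' @return An `mtumor_tree` over the same mutation set as the truth.
#' @export
perturb_tree <- function(truth, config) {
  state <- list(parent = truth$tree$parent,
                labels = truth$tree$labels,
                freq = truth$freq,
                counter = length(truth$tree$nodes))
  cap <- config$max_children_input

  # pass 1: subtree moves
  for (v in bfs_order(state_to_tree(state))) {
    if (is.na(state$parent[[v]])) next
    if (stats::runif(1) >= config$move_prob) next
    for (attempt in seq_len(10L)) {
      p <- state$parent[[v]]
      gp <- state$parent[[p]]
      sibs <- setdiff(state_children(state, p), v)
      targets <- c(if (!is.na(gp)) gp, sibs)
      if (!length(targets)) break
      tgt <- targets[[sample.int(length(targets), 1L)]]
      ch_t <- state_children(state, tgt)
      ok_branch <- length(ch_t) + 1L <= cap
      ok_sum <- state$freq[[tgt]] >=
        sum(state$freq[ch_t]) + state$freq[[v]] - 1e-12
      if (ok_branch && ok_sum) {
        state$parent[[v]] <- tgt
        break
      }
    }
  }

  # pass 2: frequency-guided edge collapses
  if (isTRUE(config$collapse)) {
    for (w in bfs_order(state_to_tree(state))) {
      if (!w %in% names(state$parent)) next
      p <- state$parent[[w]]
      if (is.na(p)) next
      p_collapse <- state$freq[[w]] / state$freq[[p]]
      if (stats::runif(1) >= p_collapse) next
      ch_w <- state_children(state, w)
      merged_children <- union(setdiff(state_children(state, p), w), ch_w)
      if (length(merged_children) > cap) next
      state$labels[[p]] <- c(state$labels[[p]], state$labels[[w]])
      for (c_ in ch_w) state$parent[[c_]] <- p
      state$parent <- state$parent[names(state$parent) != w]
      state$labels[[w]] <- NULL
      state$freq <- state$freq[names(state$freq) != w]
    }
  }

  # pass 3: expansion of multi-mutation nodes
  for (v in bfs_order(state_to_tree(state))) {
    lab <- state$labels[[v]]
    if (length(lab) < 2L) next
    if (stats::runif(1) >= config$expand_prob) next
    repeat {  # uniform split into two nonempty parts
      to_child <- stats::runif(length(lab)) < 0.5
      if (any(to_child) && !all(to_child)) break
    }
    state$counter <- state$counter + 1L
    new_id <- paste0("n", state$counter)
    ch_v <- state_children(state, v)
    state$labels[[v]] <- lab[!to_child]
    state$labels[[new_id]] <- lab[to_child]
    state$parent[[new_id]] <- v
    for (c_ in ch_v) state$parent[[c_]] <- new_id
    lo <- sum(state$freq[ch_v])
    state$freq[[new_id]] <- stats::runif(1, lo, state$freq[[v]])
  }

  state_to_tree(state)
}

#' Generate one simulation trial
#'
#' @param config A [simulation_config()].
#' @return A `trial_record`: list with `truth` (`mtumor_tree`),
#'   `frequencies` (named numeric per truth node) and `inputs` (list of
#'   `n_trees` perturbed `mtumor_tree`s over the same mutation set).
#' @export
generate_trial <- function(config) {
  truth <- random_true_tree(config$m, config)
  inputs <- lapply(seq_len(config$n_trees), function(i)
    perturb_tree(truth, config))
  structure(list(truth = truth$tree, frequencies = truth$freq,
                 inputs = inputs),
            class = "trial_record")
}

#' Generate a dataset of simulation trials
#'
#' Seeds the R random number generator from `config$seed` (when given), so
#' identical configurations reproduce identical datasets.
#'
#' @param config A [simulation_config()].
#' @return List of `trial_record` objects of length `config$n_trials`.
#' @export
generate_dataset <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  lapply(seq_len(config$n_trials), function(i) generate_trial(config))
}

#' Audit a trial against the simulator's structural guarantees
#'
#' Checks the sum rule on the ground truth (every clone's frequency is at
#' least the sum of its children's), the truth branching cap, the input
#' branching cap, and that all inputs share the truth's mutation set.
#'
#' @param trial A `trial_record`.
#' @param config The [simulation_config()] the trial was generated under.
#' @return `TRUE` invisibly; errors on any violation.
#' @export
audit_trial <- function(trial, config) {
  kids <- children_map(trial$truth)
  for (v in trial$truth$nodes) {
    ch <- kids[[v]]
    if (length(ch) > config$max_children_truth)
      mtt_error("mtt_audit_error", "truth branching cap exceeded")
    if (trial$frequencies[[v]] < sum(trial$frequencies[ch]) - 1e-9)
      mtt_error("mtt_audit_error", "sum rule violated in ground truth")
  }
  root <- root_node(trial$truth)
  if (abs(trial$frequencies[[root]] - 1) > 1e-12)
    mtt_error("mtt_audit_error", "root frequency must be 1")
  for (input in trial$inputs) {
    if (!identical(input$mutations, trial$truth$mutations))
      mtt_error("mtt_audit_error", "input over a different mutation set")
    if (max(lengths(children_map(input))) > config$max_children_input)
      mtt_error("mtt_audit_error", "input branching cap exceeded")
  }
  invisible(TRUE)
}

#' Write a dataset of trials to a directory
#'
#' Each trial gets its own subdirectory containing `truth.txt` (canonical
#' tree text), `freq.tsv` (frequency per canonical node id) and one
#' `input_XX.txt` per input tree; the dataset root gets a `manifest.json`
#' recording the configuration.
#'
#' @param trials List of `trial_record` objects.
#' @param dir Output directory (created if absent).
#' @param config The generating [simulation_config()], stored in the
#'   manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(trials, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(trials)) {
    td <- file.path(dir, sprintf("trial_%03d", i))
    dir.create(td, showWarnings = FALSE)
    trial <- trials[[i]]
    write_tree_file(trial$truth, file.path(td, "truth.txt"))
    ord <- bfs_order(trial$truth)
    utils::write.table(
      data.frame(node = seq_along(ord), frequency = trial$frequencies[ord]),
      file.path(td, "freq.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    for (j in seq_along(trial$inputs))
      write_tree_file(trial$inputs[[j]],
                      file.path(td, sprintf("input_%02d.txt", j)))
  }
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Dataset directory.
#' @return List of `trial_record` objects.
#' @export
read_dataset <- function(dir) {
  tds <- sort(list.dirs(dir, recursive = FALSE))
  lapply(tds, function(td) {
    truth <- read_tree_file(file.path(td, "truth.txt"))
    ft <- utils::read.table(file.path(td, "freq.tsv"), header = TRUE,
                            sep = "\t")
    freq <- stats::setNames(ft$frequency, as.character(ft$node))
    # truth.txt is canonical, so node ids are 1..k in bfs order
    inputs <- lapply(sort(list.files(td, pattern = "^input_",
                                     full.names = TRUE)),
                     read_tree_file)
    structure(list(truth = truth, frequencies = freq, inputs = inputs),
              class = "trial_record")
  })
}
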