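# Evaluation protocol: weighting schemes, percent change, recovery of the
# ground-truth tree, and weight-simplex sweeps.

#' Rank-based confidence weighting schemes
#'
#' Ranks the input trees by ascending AD distance to the reference
#' (ground-truth) tree, breaking ties by canonical serialization, and
#' assigns weights by rank:
#' \describe{
#'   \item{`constant`}{every tree gets `1/n` (the unweighted baseline).}
#'   \item{`naive`}{weight 1 on the closest tree, 0 elsewhere, forcing the
#'     consensus to be that single tree.}
#'   \item{`linear`}{weights decrease linearly with rank: for `n = 5`,
#'     `0.30, 0.25, 0.20, 0.15, 0.10`; for `n = 10`, starting at 0.15 and
#'     stepping down by 0.0111 (then renormalized to sum exactly to 1).
#'     Other `n` require an explicit `start` and `step`.}
#' }
#'
#' @param inputs List of `mtumor_tree` objects.
#' @param truth Reference `mtumor_tree`.
#' @param scheme One of `"constant"`, `"naive"`, `"linear"`.
#' @param start,step Optional linear-scheme parameters for `n` outside
#'   `{5, 10}`.
#' @return Numeric weights aligned with `inputs` (not with ranks).
#' @export
weighting_scheme <- function(inputs, truth,
                             scheme = c("constant", "naive", "linear"),
                             start = NULL, step = NULL) {
  scheme <- match.arg(scheme)
  n <- length(inputs)
  if (scheme == "constant") return(rep(1 / n, n))
  d <- vapply(inputs, function(t) ad_distance(t, truth), numeric(1))
  rank_order <- order(d, vapply(inputs, write_tree, character(1)))
  w <- numeric(n)
  if (scheme == "naive") {
    w[rank_order[1L]] <- 1
    return(w)
  }
  # linear
  if (is.null(start) || is.null(step)) {
    if (n == 5L) { start <- 0.30; step <- 0.05 }
    else if (n == 10L) { start <- 0.15; step <- 0.0111 }
    else mtt_error("mtt_instance_error",
                   paste0("linear scheme defaults exist only for 5 or 10 ",
                          "trees; supply start and step for n = ", n))
  }
  by_rank <- start - step * (seq_len(n) - 1L)
  if (any(by_rank <= 0))
    mtt_error("mtt_instance_error", "linear scheme weights must stay positive")
  by_rank <- by_rank / sum(by_rank)
  w[rank_order] <- by_rank
  w
}

#' Percent change of one distance relative to a reference
#'
#' `100 * (candidate - reference) / reference`: -50 means the candidate
#' total distance is half the reference's, 0 means equal, +50 means half
#' again larger.
#'
#' @param dist_candidate,dist_reference Nonnegative distances.
#' @return Percent change; 0 when both are 0, `NaN` (with a warning) when
#'   only the reference is 0.
#' @export
percent_change <- function(dist_candidate, dist_reference) {
  if (dist_reference == 0) {
    if (dist_candidate == 0) return(0)
    warning("reference distance is 0 with nonzero candidate; percent change undefined")
    return(NaN)
  }
  100 * (dist_candidate - dist_reference) / dist_reference
}

closest_input <- function(inputs, truth) {
  d <- vapply(inputs, function(t) ad_distance(t, truth), numeric(1))
  inputs[[order(d, vapply(inputs, write_tree, character(1)))[1L]]]
}

#' Run a weighting-scheme experiment over simulated trials
#'
#' For each trial and scheme, computes the weighted consensus tree, its AD
#' distance to the ground truth, and whether the truth was recovered
#' exactly (distance zero, cross-checked by tree isomorphism). The naive
#' scheme puts all weight on the closest input, whose consensus is that
#' tree itself (any tree with weight above 1/2 is the unique optimum), so
#' it is evaluated by direct selection.
#'
#' @param trials List of `trial_record` objects (or a dataset directory as
#'   written by [write_dataset()]).
#' @param schemes Subset of `c("constant", "naive", "linear")`.
#' @param time_limit Solver wall-clock limit in seconds, per trial.
#' @return List with `per_trial` (data frame: trial, scheme, distance to
#'   truth, recovered flag) and `aggregates` (data frame: scheme, mean and
#'   median distance, recovery proportion).
#' @export
run_experiment <- function(trials,
                           schemes = c("naive", "constant", "linear"),
                           time_limit = 600) {
  if (is.character(trials)) trials <- read_dataset(trials)
  schemes <- match.arg(schemes, several.ok = TRUE)
  rows <- list()
  for (scheme in schemes) {
    if (scheme == "naive") {
      cons <- lapply(trials, function(tr)
        closest_input(tr$inputs, tr$truth))
    } else {
      instances <- lapply(trials, function(tr)
        weighted_instance(tr$inputs,
                          weighting_scheme(tr$inputs, tr$truth, scheme)))
      cons <- lapply(consensus_batch(instances, time_limit = time_limit),
                     function(res) res$trees[[1L]])
    }
    d <- mapply(function(tree, tr) ad_distance(tree, tr$truth),
                cons, trials)
    recovered <- mapply(function(tree, tr) trees_equal(tree, tr$truth),
                        cons, trials)
    if (any(recovered != (d == 0)))
      mtt_error("mtt_audit_error",
                "recovery flag and zero AD distance disagree")
    rows[[scheme]] <- data.frame(trial = seq_along(trials), scheme = scheme,
                                 distance = d, recovered = recovered)
  }
  per_trial <- do.call(rbind, rows)
  rownames(per_trial) <- NULL
  aggregates <- do.call(rbind, lapply(split(per_trial, per_trial$scheme),
    function(df) data.frame(scheme = df$scheme[1L],
                            mean_distance = mean(df$distance),
                            median_distance = stats::median(df$distance),
                            recovery = mean(df$recovered))))
  rownames(aggregates) <- NULL
  list(per_trial = per_trial, aggregates = aggregates)
}

#' Enumerate the weight grid on the probability simplex
#' @param n Number of weights.
#' @param step Grid step; must divide 1.
#' @return Matrix with one weight vector per row, rows summing to 1.
#' @export
simplex_grid <- function(n, step = 0.1) {
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-9)
    mtt_error("mtt_instance_error", "step must divide 1")
  compositions <- function(total, parts) {
    if (parts == 1L) return(matrix(total, ncol = 1))
    out <- list()
    for (first in 0:total) {
      rest <- compositions(total - first, parts - 1L)
      out[[length(out) + 1L]] <- cbind(first, rest)
    }
    do.call(rbind, out)
  }
  g <- compositions(k, n) / k
  dimnames(g) <- NULL
  g
}

#' Sweep consensus solutions across the weight simplex
#'
#' Runs all-optima consensus at every grid point of the weight simplex and
#' groups grid points by the set of optimal trees they produce, supporting
#' ternary-style maps of how the consensus changes with confidence weights.
#'
#' @param trees List of `mtumor_tree` objects (the instance).
#' @param step Simplex grid step (default 0.1).
#' @param limit Per-point cap on enumerated optima.
#' @param time_limit Solver wall-clock limit in seconds, per grid point.
#' @return List with `grid` (data frame: one row per grid point with the
#'   weights, the optimum-set id, optimum count, truncation flag) and
#'   `optima_sets` (list mapping set id to the list of optimal trees).
#' @export
weight_sweep <- function(trees, step = 0.1, limit = 100L, time_limit = 600) {
  n <- length(trees)
  grid <- simplex_grid(n, step)
  set_key <- character(nrow(grid))
  counts <- integer(nrow(grid))
  truncated <- logical(nrow(grid))
  sets <- list()
  for (i in seq_len(nrow(grid))) {
    res <- consensus(trees, weights = grid[i, ], all_optima = TRUE,
                     limit = limit, time_limit = time_limit)
    key <- paste(vapply(res$trees, write_tree, character(1)),
                 collapse = "\x1d")
    if (is.null(sets[[key]])) sets[[key]] <- res$trees
    set_key[i] <- key
    counts[i] <- length(res$trees)
    truncated[i] <- res$truncated
  }
  ids <- stats::setNames(seq_along(sets), names(sets))
  df <- data.frame(grid)
  names(df) <- paste0("w", seq_len(n))
  df$optima_set <- unname(ids[set_key])
  df$n_optima <- counts
  df$truncated <- truncated
  list(grid = df, optima_sets = stats::setNames(unname(sets),
                                                seq_along(sets)))
}
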