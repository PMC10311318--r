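# Integer linear program over ancestral-relation variables.
#
# For each ordered pair of distinct mutations (a, b) a binary variable x_ab
# encodes "a is ancestral to b" in the consensus tree; binary r_a encodes "a
# labels the root". Linear constraints force the x variables to be the
# transitive closure of a valid m-tumor tree:
#   transitivity      x_ac >= x_ab + x_bc - 1           (all distinct triples)
#   single lineage    x_ab + x_ba >= x_ac + x_bc - 1    (all distinct triples)
#   rooted            sum_a r_a >= 1
#   root is ancestral sum_b x_ab >= (m-1) r_a           (per mutation)
#   non-roots are not sum_b x_ab - (m-2) <= r_a         (per mutation)
# Minimizing sum_ab x_ab (1 - 2 s_ab), with s_ab the weighted fraction of
# input trees having a ancestral to b, minimizes the total weighted AD
# distance up to the constant sum_i w_i |phi_AD(T_i)|.

# weighted delta-support over the instance, from trees or raw pair sets
support_from_pairs <- function(pair_sets, weights, mutations) {
  m <- length(mutations)
  support <- matrix(0, m, m, dimnames = list(mutations, mutations))
  constant <- 0
  for (i in seq_along(pair_sets)) {
    delta <- pairs_to_relation(pair_sets[[i]], mutations)
    support <- support + weights[i] * delta
    constant <- constant + weights[i] * sum(delta)
  }
  structure(list(mutations = mutations, support = support,
                 constant = constant),
            class = "support_matrix")
}

#' Weighted ancestral-pair support of an instance
#'
#' For each ordered mutation pair `(a, b)`, the support is the total weight
#' of input trees in which `a` is ancestral to `b`. The constant term is
#' the weighted sum of the input trees' AD-pair counts; together they give
#' the ILP objective `constant + sum x_ab (1 - 2 support_ab)`.
#'
#' @param instance A [weighted_instance()].
#' @return A `support_matrix` object with fields `mutations`, `support`
#'   (m-by-m matrix, zero diagonal) and `constant`.
#' @export
support_matrix <- function(instance) {
  stopifnot(inherits(instance, "weighted_instance"))
  support_from_pairs(lapply(instance$trees, ad_pairs),
                     instance$weights, instance$mutations)
}

# variable indexing: x variables for ordered pairs (a, b), a != b, in
# row-major order over sorted mutations with the diagonal skipped, followed
# by the m root indicators.
xvar_index <- function(m) {
  idx <- matrix(NA_integer_, m, m)
  k <- 0L
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a != b) { k <- k + 1L; idx[a, b] <- k }
  }
  idx
}

#' Build the consensus ILP model for a weighted instance
#'
#' Instantiates the ancestral-relation variables, the transitivity and
#' single-lineage constraints over all ordered triples of distinct
#' mutations, and the root constraints. For `m = 1` no solver is needed
#' (the single-node tree is the unique m-tumor tree) and a trivial marker
#' model is returned.
#'
#' @param instance A [weighted_instance()], or a `support_matrix`.
#' @return A `consensus_model` list with the variable maps, sparse
#'   constraint triplets, objective vector and constant term.
#' @export
build_model <- function(instance) {
  sm <- if (inherits(instance, "support_matrix")) instance
        else support_matrix(instance)
  muts <- sm$mutations
  m <- length(muts)
  if (m == 0L) mtt_error("mtt_model_error", "empty mutation set")
  if (m == 1L) {
    return(structure(list(trivial = TRUE, mutations = muts,
                          constant = sm$constant),
                     class = "consensus_model"))
  }
  xidx <- xvar_index(m)
  nx <- m * (m - 1L)
  nv <- nx + m
  ridx <- nx + seq_len(m)

  triples <- expand.grid(c = seq_len(m), b = seq_len(m), a = seq_len(m))
  triples <- triples[triples$a != triples$b & triples$b != triples$c &
                     triples$a != triples$c, c("a", "b", "c")]
  nt <- nrow(triples)

  # transitivity: x_ac - x_ab - x_bc >= -1
  r1 <- seq_len(nt)
  i1 <- rep(r1, 3L)
  j1 <- c(xidx[cbind(triples$a, triples$c)],
          xidx[cbind(triples$a, triples$b)],
          xidx[cbind(triples$b, triples$c)])
  v1 <- rep(c(1, -1, -1), each = nt)
  # single lineage: x_ab + x_ba - x_ac - x_bc >= -1
  r2 <- nt + seq_len(nt)
  i2 <- rep(r2, 4L)
  j2 <- c(xidx[cbind(triples$a, triples$b)],
          xidx[cbind(triples$b, triples$a)],
          xidx[cbind(triples$a, triples$c)],
          xidx[cbind(triples$b, triples$c)])
  v2 <- rep(c(1, 1, -1, -1), each = nt)
  row_lb <- rep(-1, 2L * nt)
  row_ub <- rep(Inf, 2L * nt)

  # at least one root mutation
  r3 <- 2L * nt + 1L
  i3 <- rep(r3, m); j3 <- ridx; v3 <- rep(1, m)
  row_lb <- c(row_lb, 1); row_ub <- c(row_ub, Inf)

  # per-mutation root coupling
  i4 <- integer(0); j4 <- integer(0); v4 <- numeric(0)
  nextrow <- r3
  for (a in seq_len(m)) {
    others <- setdiff(seq_len(m), a)
    # sum_b x_ab - (m-1) r_a >= 0
    nextrow <- nextrow + 1L
    i4 <- c(i4, rep(nextrow, m))
    j4 <- c(j4, xidx[cbind(a, others)], ridx[a])
    v4 <- c(v4, rep(1, m - 1L), -(m - 1L))
    row_lb <- c(row_lb, 0); row_ub <- c(row_ub, Inf)
    # sum_b x_ab - r_a <= m - 2
    nextrow <- nextrow + 1L
    i4 <- c(i4, rep(nextrow, m))
    j4 <- c(j4, xidx[cbind(a, others)], ridx[a])
    v4 <- c(v4, rep(1, m - 1L), -1)
    row_lb <- c(row_lb, -Inf); row_ub <- c(row_ub, m - 2L)
  }

  obj <- numeric(nv)
  ut <- which(upper.tri(sm$support) | lower.tri(sm$support), arr.ind = TRUE)
  obj[xidx[ut]] <- 1 - 2 * sm$support[ut]

  structure(list(trivial = FALSE, mutations = muts, m = m,
                 xidx = xidx, ridx = ridx, nvars = nv,
                 obj = obj,
                 con_i = c(i1, i2, i3, i4),
                 con_j = c(j1, j2, j3, j4),
                 con_v = c(v1, v2, v3, v4),
                 row_lb = row_lb, row_ub = row_ub,
                 constant = sm$constant),
            class = "consensus_model")
}

assignment_to_solution <- function(model, assignment, objective) {
  muts <- model$mutations
  m <- model$m
  x <- matrix(0L, m, m, dimnames = list(muts, muts))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a != b) x[a, b] <- assignment[model$xidx[a, b]]
  }
  r <- assignment[model$ridx]
  names(r) <- muts
  structure(list(mutations = muts, x = x, r = r,
                 objective_value = model$constant + objective),
            class = "relation_solution")
}

trivial_solution <- function(model) {
  mut <- model$mutations
  structure(list(mutations = mut,
                 x = matrix(0L, 1, 1, dimnames = list(mut, mut)),
                 r = stats::setNames(1L, mut),
                 objective_value = model$constant),
            class = "relation_solution")
}

#' Audit a relation solution against the ILP constraints
#'
#' Re-checks, in integer arithmetic and independently of the solver, that a
#' solution satisfies transitivity, the single-lineage condition, and the
#' root constraints.
#'
#' @param sol A `relation_solution`.
#' @return The solution, invisibly; errors on any violation.
#' @export
audit_relation_solution <- function(sol) {
  x <- sol$x
  m <- nrow(x)
  if (m > 1L) {
    # transitivity via boolean matrix product: reachable-in-2 implies edge
    x2 <- (x %*% x) > 0
    diag(x2) <- FALSE
    if (any(x2 & x != 1L))
      mtt_error("mtt_audit_error", "solution violates transitivity")
    # single lineage: common descendant implies comparable ancestors
    for (c_ in seq_len(m)) {
      anc <- which(x[, c_] == 1L)
      if (length(anc) > 1L) {
        combs <- utils::combn(anc, 2L)
        for (k in seq_len(ncol(combs))) {
          a <- combs[1L, k]; b <- combs[2L, k]
          if (x[a, b] + x[b, a] < 1L)
            mtt_error("mtt_audit_error",
                      "solution violates the single-lineage condition")
        }
      }
    }
  }
  outdeg <- rowSums(x)
  expected_r <- as.integer(outdeg == m - 1L)
  if (!all(sol$r == expected_r))
    mtt_error("mtt_audit_error",
              "root indicators inconsistent with ancestral out-degrees")
  if (sum(sol$r) < 1L)
    mtt_error("mtt_audit_error", "no root mutation in solution")
  invisible(sol)
}

model_problem <- function(model, limit, probe) {
  list(nvars = model$nvars, obj = model$obj,
       con_i = model$con_i, con_j = model$con_j, con_v = model$con_v,
       row_lb = model$row_lb, row_ub = model$row_ub,
       cut_vars = model$xidx[!is.na(model$xidx)],
       limit = limit, probe = probe)
}

solutions_from_result <- function(model, res) {
  if (!identical(res$status, "optimal"))
    mtt_error("mtt_solver_error",
              paste0("solver did not reach optimality (status: ",
                     res$status, ")"))
  sols <- lapply(res$solutions, function(a)
    audit_relation_solution(assignment_to_solution(model, a, res$objective)))
  list(solutions = sols, truncated = res$truncated)
}

#' Solve the consensus ILP
#'
#' @param model A `consensus_model` from [build_model()].
#' @param time_limit Solver wall-clock limit in seconds.
#' @return A `relation_solution`: the optimal ancestral relation, root
#'   indicators, and the objective value on the weighted-AD-distance scale
#'   (constant term included).
#' @export
solve_model <- function(model, time_limit = 600) {
  stopifnot(inherits(model, "consensus_model"))
  if (isTRUE(model$trivial)) return(trivial_solution(model))
  res <- milp_solve_batch(list(model_problem(model, 1L, FALSE)),
                          time_limit = time_limit)[[1L]]
  solutions_from_result(model, res)$solutions[[1L]]
}

#' Enumerate all optimal solutions of the consensus ILP
#'
#' Repeatedly re-solves the model after adding a no-good cut that excludes
#' each found assignment of the ancestral-relation variables, until the
#' objective strictly worsens or `limit` solutions have been found. Since
#' distinct feasible x-assignments are in bijection with m-tumor trees
#' (each is the transitive closure of a unique tree), this enumerates
#' distinct co-optimal consensus trees.
#'
#' @param model A `consensus_model`.
#' @param limit Maximum number of optima to return.
#' @param time_limit Solver wall-clock limit in seconds (whole enumeration).
#' @return List with `solutions` (list of `relation_solution`) and
#'   `truncated` (`TRUE` when more optima exist beyond `limit`).
#' @export
enumerate_optima <- function(model, limit = 100L, time_limit = 600) {
  stopifnot(inherits(model, "consensus_model"), limit >= 1L)
  if (isTRUE(model$trivial))
    return(list(solutions = list(trivial_solution(model)), truncated = FALSE))
  res <- milp_solve_batch(list(model_problem(model, as.integer(limit), TRUE)),
                          time_limit = time_limit)[[1L]]
  solutions_from_result(model, res)
}
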