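# Thin batched interface to a mixed-integer linear programming solver.
# Models are exchanged with a Python worker (scipy's HiGHS front end) as
# JSON; one worker invocation solves a whole batch of models, and can
# enumerate co-optimal binary assignments via no-good cuts.

#' Locate the Python interpreter used for the MILP backend
#'
#' Resolution order: option `mtumortree.python`, environment variable
#' `MTUMORTREE_PYTHON`, then `python3` / `python` on the `PATH`.
#' @return Path to the interpreter.
#' @export
find_python <- function() {
  cand <- getOption("mtumortree.python",
                    Sys.getenv("MTUMORTREE_PYTHON", unset = NA))
  if (!is.na(cand) && nzchar(cand)) return(cand)
  for (p in c("python3", "python")) {
    hit <- Sys.which(p)
    if (nzchar(hit)) return(unname(hit))
  }
  mtt_error("mtt_solver_error",
            "no python interpreter found for the MILP backend")
}

# problems: list of models, each a list with
#   nvars    : number of binary variables
#   obj      : objective coefficients (minimize)
#   con_i, con_j, con_v : constraint matrix triplets (1-based)
#   row_lb, row_ub : row bounds (use -Inf/Inf for one-sided)
#   cut_vars : 1-based indices of the variables the no-good cuts range over
#   limit    : max number of optima to enumerate (1 = just solve)
# Returns a list (one element per problem) with fields
#   status, objective, solutions (list of 0/1 vectors), truncated.
milp_solve_batch <- function(problems, time_limit = 600, obj_tol = 1e-6) {
  stopifnot(length(problems) > 0)
  payload <- list(
    time_limit = time_limit,
    obj_tol = obj_tol,
    problems = lapply(problems, function(p) {
      list(nvars = p$nvars,
           obj = as.numeric(p$obj),
           con_i = as.integer(p$con_i) - 1L,
           con_j = as.integer(p$con_j) - 1L,
           con_v = as.numeric(p$con_v),
           row_lb = ifelse(is.finite(p$row_lb), p$row_lb, -1e30),
           row_ub = ifelse(is.finite(p$row_ub), p$row_ub, 1e30),
           cut_vars = as.integer(p$cut_vars) - 1L,
           limit = as.integer(p$limit %||% 1L),
           probe = isTRUE(p$probe))
    })
  )
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_solve.py", package = "mtumortree")
  if (!nzchar(script))
    mtt_error("mtt_solver_error", "bundled MILP worker script not found")
  status <- system2(find_python(), c(shQuote(script), shQuote(infile),
                                     shQuote(outfile)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(outfile))
    mtt_error("mtt_solver_error",
              paste0("MILP worker failed:\n", paste(status, collapse = "\n")))
  res <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  lapply(res, function(r) {
    list(status = r$status,
         objective = if (is.null(r$objective)) NA_real_ else r$objective,
         solutions = lapply(r$solutions, function(s)
           as.integer(round(unlist(s)))),
         truncated = isTRUE(r$truncated))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
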