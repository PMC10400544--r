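## Mixed-integer linear programming layer.
##
## Problems are built as plain R lists (triplet-sparse constraint matrix) and
## solved in batches by the HiGHS solver, reached through the scipy front end
## of a python worker process (inst/python/milp_bridge.py). Batching matters:
## one worker invocation can solve hundreds of small instances, so sweeps and
## the exhaustive oracle pay the interpreter start-up cost once.

#' Create an empty MILP problem
#'
#' Internal builder used by the driving-force MILPs and the reference oracle.
#' Variables are identified by name; constraints are stored as sparse rows with
#' two-sided bounds (`lb <= a'x <= ub`).
#'
#' @param varNames character vector of variable names.
#' @param maximize logical; direction of optimization.
#' @return a list with the problem skeleton.
#' @keywords internal
milpProblem <- function(varNames, maximize = TRUE) {
  n <- length(varNames)
  list(
    varNames = varNames,
    varIndex = stats::setNames(seq_len(n), varNames),
    obj = numeric(n),
    varLb = rep(-Inf, n),
    varUb = rep(Inf, n),
    integrality = integer(n),
    maximize = maximize,
    rows = list()
  )
}

## Set variable bounds / objective / binary flag by name.
mpSetBounds <- function(p, vars, lb = NULL, ub = NULL) {
  i <- p$varIndex[vars]
  if (anyNA(i)) stop("unknown variable(s): ", paste(vars[is.na(i)], collapse = ", "))
  if (!is.null(lb)) p$varLb[i] <- lb
  if (!is.null(ub)) p$varUb[i] <- ub
  p
}

mpSetObjective <- function(p, vars, coef) {
  i <- p$varIndex[vars]
  p$obj[i] <- coef
  p
}

mpSetBinary <- function(p, vars) {
  i <- p$varIndex[vars]
  p$integrality[i] <- 1L
  p$varLb[i] <- 0
  p$varUb[i] <- 1
  p
}

## Add a row lb <= sum(coef * vars) <= ub.
mpAddRow <- function(p, vars, coef, lb = -Inf, ub = Inf) {
  i <- p$varIndex[vars]
  if (anyNA(i)) stop("unknown variable(s): ", paste(vars[is.na(i)], collapse = ", "))
  p$rows[[length(p$rows) + 1L]] <- list(j = unname(i), v = unname(coef),
                                        lb = lb, ub = ub)
  p
}

## Serialize one problem for the worker.
mpSerialize <- function(p) {
  nr <- length(p$rows)
  ri <- integer(0); rj <- integer(0); rv <- numeric(0)
  clb <- numeric(nr); cub <- numeric(nr)
  if (nr) {
    lens <- vapply(p$rows, function(r) length(r$j), 0L)
    ri <- rep.int(seq_len(nr), lens)
    rj <- unlist(lapply(p$rows, `[[`, "j"), use.names = FALSE)
    rv <- unlist(lapply(p$rows, `[[`, "v"), use.names = FALSE)
    clb <- vapply(p$rows, `[[`, 0, "lb")
    cub <- vapply(p$rows, `[[`, 0, "ub")
  }
  cap <- function(x) { x[x == Inf] <- 1e30; x[x == -Inf] <- -1e30; x }
  list(
    n_var = length(p$obj),
    n_con = nr,
    obj = as.list(p$obj),
    maximize = isTRUE(p$maximize),
    var_lb = as.list(cap(p$varLb)),
    var_ub = as.list(cap(p$varUb)),
    integrality = as.list(p$integrality),
    A_i = as.list(ri), A_j = as.list(rj), A_v = as.list(rv),
    con_lb = as.list(cap(clb)), con_ub = as.list(cap(cub))
  )
}

#' Locate the python interpreter used by the solver backend
#'
#' Honours `options(tcosa.python = ...)`, then the `TCOSA_PYTHON` environment
#' variable, then `python` on the PATH.
#' @return path to the interpreter.
#' @keywords internal
pythonBinary <- function() {
  p <- getOption("tcosa.python", "")
  if (!nzchar(p)) p <- Sys.getenv("TCOSA_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) stop("no python interpreter found for the MILP backend")
  p
}

#' Solve a batch of MILP problems
#'
#' @param problems list of problems built with [milpProblem()] and the `mp*`
#'   helpers.
#' @param config a [MilpConfig-class]; only `"highs"` is shipped as backend.
#' @return a list (one element per problem) with `status`
#'   (`optimal`/`infeasible`/`unbounded`/`error`), `objective`, and named
#'   solution vector `x`.
#' @keywords internal
solveMilpBatch <- function(problems, config = milpConfig()) {
  if (!length(problems)) return(list())
  if (!identical(config@solver, "highs"))
    stop("unknown solver backend: ", config@solver)
  script <- system.file("python", "milp_bridge.py", package = "tcosa")
  if (!nzchar(script)) stop("milp_bridge.py not found; is the package installed?")
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  payload <- list(
    options = list(mip_rel_gap = 0,
                   primal_feasibility_tolerance = config@feasTol,
                   mip_integrality_tolerance = config@intTol),
    problems = lapply(problems, mpSerialize)
  )
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(pythonBinary(), c(script, fin, fout),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(fout))
    stop("MILP worker failed:\n", paste(status, collapse = "\n"))
  res <- jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(seq_along(problems), function(k) {
    r <- res[[k]]
    x <- as.numeric(r$x %||% rep(NA_real_, length(problems[[k]]$obj)))
    names(x) <- problems[[k]]$varNames
    list(status = r$status, objective = as.numeric(r$objective %||% NA_real_), x = x)
  })
}

## Convenience wrapper for a single problem.
solveMilp <- function(problem, config = milpConfig()) {
  solveMilpBatch(list(problem), config)[[1L]]
}
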