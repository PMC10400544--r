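## Plain flux balance analysis (no thermodynamic constraints).

## LP over fluxes only: steady state + bounds, maximize one flux.
fbaProblem <- function(model, maximizeRxn, blocked = character(0),
                       growthMin = NULL) {
  rxns <- model@rxnId
  p <- milpProblem(paste0("r_", rxns), maximize = TRUE)
  lb <- pmax(model@lb, 0); ub <- model@ub
  lb[blocked] <- 0; ub[blocked] <- 0
  if (!is.null(growthMin)) {
    g <- model@objectiveReaction
    lb[g] <- max(lb[g], growthMin)
  }
  p <- mpSetBounds(p, paste0("r_", rxns), lb = unname(lb), ub = unname(ub))
  internal <- model@metId[!model@metExternal]
  byMet <- stats::setNames(vector("list", length(internal)), internal)
  for (j in seq_along(rxns)) {
    s <- model@stoich[[j]]
    for (mm in intersect(names(s), internal))
      byMet[[mm]] <- c(byMet[[mm]], stats::setNames(s[[mm]], rxns[j]))
  }
  for (mm in internal) {
    row <- byMet[[mm]]
    if (is.null(row)) next
    p <- mpAddRow(p, paste0("r_", names(row)), unname(row), lb = 0, ub = 0)
  }
  mpSetObjective(p, paste0("r_", maximizeRxn), 1)
}

#' Maximal growth rate by flux balance analysis
#'
#' LP-maximizes the objective (growth) flux subject to steady-state mass
#' balance and flux bounds, without thermodynamic constraints. For a
#' [TcosaModel-class] an optional [SpecificityAssignment-class] is applied
#' first (variants blocked per scenario).
#'
#' @param model a [MetabolicModel-class] or [TcosaModel-class].
#' @param assignment optional [SpecificityAssignment-class] (TcosaModel only).
#' @param config a [MilpConfig-class].
#' @return list with `growth` (h^-1, `NA` when infeasible), `status`, and the
#'   optimal `fluxes`.
#' @export
maxGrowth <- function(model, assignment = NULL, config = milpConfig()) {
  if (methods::is(model, "TcosaModel")) {
    if (!is.null(assignment)) model <- applyScenario(model, assignment)
    mm <- model@model
  } else {
    if (!is.null(assignment))
      stop("specificity assignments apply to TcosaModel objects only")
    mm <- model
  }
  if (any(mm@lb < 0))
    stop("maxGrowth expects an irreversible model; run splitReversible() first")
  p <- fbaProblem(mm, mm@objectiveReaction)
  res <- solveMilp(p, config)
  if (!identical(res$status, "optimal"))
    return(list(growth = NA_real_, status = res$status, fluxes = numeric(0)))
  fl <- res$x
  names(fl) <- mm@rxnId
  list(growth = unname(res$objective), status = "optimal", fluxes = fl)
}
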