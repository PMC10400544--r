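## Minimal-relaxation feasibility repair.

#' Relax the fewest driving-force constraints to make growth feasible
#'
#' When growth at the demanded rate is stoichiometrically possible but the
#' MDF optimum falls below `bMin`, solves a MILP minimizing the number of
#' reactions whose driving-force constraint is dropped so that a solution with
#' `B >= bMin` exists at that growth rate. The returned model has the relaxed
#' reactions retagged `relaxed` and excluded from all subsequent driving-force
#' constraints (they are treated as fully thermodynamically unconstrained).
#'
#' @param tcosa a [TcosaModel-class].
#' @param demandedGrowth growth-rate lower bound (h^-1).
#' @param bMin feasibility floor (kJ/mol).
#' @param config a [MilpConfig-class].
#' @return list with `relaxed` (reaction ids, possibly empty) and `model`
#'   (the retagged [TcosaModel-class]).
#' @export
relaxToFeasibility <- function(tcosa, demandedGrowth, bMin = 0.1,
                               config = milpConfig()) {
  fba <- maxGrowth(tcosa)
  if (!identical(fba$status, "optimal") || fba$growth < demandedGrowth - 1e-9)
    stop("infeasibility error: growth of ", demandedGrowth,
         " h^-1 is stoichiometrically infeasible (FBA maximum: ",
         if (identical(fba$status, "optimal")) signif(fba$growth, 6) else fba$status,
         ")")
  base <- solveMdf(tcosa, constraints = list(growthMin = demandedGrowth), config)
  if (identical(base@status, "optimal") && base@B >= bMin)
    return(list(relaxed = character(0), model = tcosa))

  ids <- thermoConstrained(tcosa)
  prob <- buildDfProblem(tcosa, constraints = list(growthMin = demandedGrowth),
                         config = config, objective = "relaxCount",
                         relaxable = ids)
  prob <- mpSetBounds(prob, "B", lb = bMin)
  res <- solveMilp(prob, config)
  if (!identical(res$status, "optimal"))
    stop("thermodynamic infeasibility: no relaxation set achieves B >= ", bMin)
  u <- res$x[paste0("u_", ids)]
  relaxed <- ids[u > 0.5]

  thermo <- tcosa@thermo
  dg <- thermo@dG0[setdiff(names(thermo@dG0), relaxed)]
  tags <- thermo@dG0Tag
  tags[relaxed] <- "relaxed"
  ta <- tcosa@thermoActive
  ta[relaxed] <- FALSE
  model <- methods::initialize(tcosa,
    thermo = methods::initialize(thermo, dG0 = dg, dG0Tag = tags),
    thermoActive = ta)
  list(relaxed = relaxed, model = model)
}
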