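## Single-swap scanning and the minimal cofactor-swap MILP.

## complementary (swapped-specificity) variant ids for a wild-type-like
## assignment, named by derived reaction id, value = original reaction id
complementarySet <- function(tc, assignment) {
  prov <- tc@provenance
  out <- character(0)
  pools2 <- names(tc@cofactors@pools)[1:2]
  for (k in names(assignment@choices)) {
    choice <- assignment@choices[[k]]
    if (!(choice %in% pools2)) next
    other <- setdiff(pools2, choice)
    members <- prov[prov$original == k & !is.na(prov$pool) & prov$pool == other, ,
                    drop = FALSE]
    out <- c(out, stats::setNames(rep(k, nrow(members)), members$id))
  }
  out
}

#' Effect of single cofactor swaps on the (Sub)MDF
#'
#' For each duplicated redox reaction, flips its cofactor specificity
#' (original variant deactivated, swapped variant activated), re-solves the
#' (Sub)MDF at every growth set point and records the change relative to the
#' unswapped assignment. Swaps making the demanded growth stoichiometrically
#' infeasible are flagged and excluded from the deltas.
#'
#' @param tcosa a [TcosaModel-class].
#' @param assignment the reference [SpecificityAssignment-class]
#'   (typically [wildTypeAssignment()]).
#' @param grid growth set points.
#' @param objective `"MDF"` or `"SubMDF"`.
#' @param config a [MilpConfig-class].
#' @return data.frame with columns `reaction` (original id), `growth`,
#'   `objective`, `base`, `value`, `delta`, `feasible`.
#' @export
singleSwapScan <- function(tcosa, assignment, grid,
                           objective = c("MDF", "SubMDF"),
                           config = milpConfig()) {
  objective <- match.arg(objective)
  pools2 <- names(tcosa@cofactors@pools)[1:2]
  swappable <- names(assignment@choices)[assignment@choices %in% pools2]
  out <- list()
  for (g in as.numeric(grid)) {
    cons <- list(growthMin = g)
    mkSolve <- function(tc) {
      if (objective == "MDF") solveMdf(tc, cons, config)
      else solveSubMdf(tc, redoxSubset(tc), cons, config)
    }
    baseSol <- mkSolve(applyScenario(tcosa, assignment))
    baseVal <- if (!identical(baseSol@status, "optimal")) NA_real_
               else if (objective == "MDF") baseSol@B else baseSol@BSub
    for (k in swappable) {
      flipped <- assignment
      flipped@choices[[k]] <- setdiff(pools2, assignment@choices[[k]])
      tc <- applyScenario(tcosa, flipped)
      feas <- maxGrowth(tc, config = config)
      ok <- identical(feas$status, "optimal") && feas$growth >= g - 1e-9
      val <- NA_real_
      if (ok) {
        sol <- mkSolve(tc)
        if (identical(sol@status, "optimal"))
          val <- if (objective == "MDF") sol@B else sol@BSub
        else ok <- FALSE
      }
      out[[length(out) + 1L]] <- data.frame(
        reaction = k, growth = g, objective = objective, base = baseVal,
        value = val, delta = val - baseVal, feasible = ok,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Minimal number of cofactor swaps to reach a driving-force target
#'
#' Starting from a reference (wild-type) specificity, opens every
#' complementary-specificity variant behind a swap indicator and minimizes
#' the number of indicators switched on, subject to the full driving-force
#' constraints and the demanded (Sub)MDF target (imposed as
#' `>= target - band` to avoid MILP equality brittleness). When the target is
#' the flexible-scenario optimum of the same instance, a solution always
#' exists; a count of zero certifies that the reference specificity already
#' attains the flexible optimum.
#'
#' @param tcosa a [TcosaModel-class].
#' @param assignment the reference [SpecificityAssignment-class].
#' @param target demanded (Sub)MDF value (kJ/mol), typically the flexible
#'   optimum at the same set point.
#' @param growth growth set point (h^-1).
#' @param objective `"MDF"` or `"SubMDF"`.
#' @param config a [MilpConfig-class].
#' @param band target tolerance (kJ/mol).
#' @return list with `count`, `swaps` (original reaction ids), `status`.
#' @export
minSwapsToTarget <- function(tcosa, assignment, target, growth,
                             objective = c("MDF", "SubMDF"),
                             config = milpConfig(),
                             band = MDF_EQUALITY_BAND) {
  objective <- match.arg(objective)
  comp <- complementarySet(tcosa, assignment)
  ## block everything the scenario blocks, then re-open the complementary
  ## variants behind swap indicators at their native upper bounds
  scen <- applyScenario(tcosa, assignment)
  swapUb <- tcosa@model@ub[names(comp)]
  subset <- if (objective == "SubMDF") redoxSubset(scen) else NULL
  prob <- buildDfProblem(
    scen, constraints = list(growthMin = growth), config = config,
    objective = list(vars = paste0("w_", names(comp)),
                     coefs = rep(1, length(comp)), maximize = FALSE),
    subset = subset,
    fixLevel = list(kind = if (objective == "MDF") "B" else "BSub",
                    value = target, band = band),
    swapSet = swapUb)
  res <- solveMilp(prob, config)
  if (!identical(res$status, "optimal"))
    return(list(count = NA_integer_, swaps = character(0), status = res$status))
  w <- res$x[paste0("w_", names(comp))]
  flipped <- names(comp)[w > 0.5]
  list(count = length(flipped), swaps = unique(unname(comp[flipped])),
       status = "optimal")
}
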