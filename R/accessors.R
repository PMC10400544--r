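## Accessors and show methods. Slot access outside this file is discouraged;
## analysis code goes through these.

#' @describeIn MetabolicModel-class metabolite table (id, external, compartment).
#' @param object,x an object of the documented class.
#' @export
setMethod("metabolites", "MetabolicModel", function(object, ...) {
  data.frame(id = object@metId, external = object@metExternal,
             compartment = object@metCompartment, stringsAsFactors = FALSE)
})

#' @describeIn MetabolicModel-class reaction table (id, lb, ub, reversible).
#' @export
setMethod("reactions", "MetabolicModel", function(object, ...) {
  data.frame(id = object@rxnId, lb = unname(object@lb), ub = unname(object@ub),
             reversible = unname(object@reversible), stringsAsFactors = FALSE)
})

#' @describeIn MetabolicModel-class stoichiometry of one reaction (named
#'   numeric) or, with `reaction = NULL`, the full dense matrix
#'   (metabolites x reactions).
#' @param reaction a reaction id or `NULL`.
#' @export
setMethod("stoichiometry", "MetabolicModel", function(object, reaction = NULL, ...) {
  if (!is.null(reaction)) {
    if (!reaction %in% object@rxnId) stop("unknown reaction: ", reaction)
    return(object@stoich[[reaction]])
  }
  S <- matrix(0, length(object@metId), length(object@rxnId),
              dimnames = list(object@metId, object@rxnId))
  for (j in seq_along(object@rxnId)) {
    s <- object@stoich[[j]]
    S[names(s), j] <- s
  }
  S
})

#' @describeIn MetabolicModel-class two-column matrix of flux bounds.
#' @export
setMethod("fluxBounds", "MetabolicModel", function(object, ...) {
  cbind(lb = object@lb, ub = object@ub)
})

#' @describeIn MetabolicModel-class id of the objective pseudo-reaction.
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(object) object@objectiveReaction)

#' @describeIn MetabolicModel-class ids of exchange pseudo-reactions.
#' @export
setMethod("exchangeReactions", "MetabolicModel", function(object) object@exchangeReactions)

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d reactions (%d reversible), %d metabolites (%d external)\n",
              length(object@rxnId), sum(object@reversible),
              length(object@metId), sum(object@metExternal)))
  cat(sprintf("  objective: %s; %d exchange reactions\n",
              object@objectiveReaction, length(object@exchangeReactions)))
})

#' @describeIn ThermoAnnotation-class standard Gibbs energies (named numeric).
#' @param object,x an object of the documented class.
#' @export
setMethod("dG0", "ThermoAnnotation", function(object, ...) object@dG0)

#' @describeIn ThermoAnnotation-class provenance tags per annotated reaction.
#' @export
setMethod("dG0Tags", "ThermoAnnotation", function(object, ...) object@dG0Tag)

#' @describeIn ThermoAnnotation-class two-column matrix of molar bounds.
#' @export
setMethod("concentrationBounds", "ThermoAnnotation", function(object, ...) {
  cbind(cMin = object@cMin, cMax = object@cMax)
})

setMethod("show", "ThermoAnnotation", function(object) {
  cat(sprintf("ThermoAnnotation: %d dG0 entries, %d metabolite concentration ranges\n",
              length(object@dG0), length(object@cMin)))
  if (length(object@dG0Tag)) {
    tb <- table(object@dG0Tag)
    cat("  tags:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  cat(sprintf("  T = %.2f K; %d species fixed at 1 M\n",
              object@temperature, length(object@fixedUnitSpecies)))
})

#' @describeIn CofactorSpec-class named list of cofactor pools.
#' @param object,x an object of the documented class.
#' @export
setMethod("cofactorPools", "CofactorSpec", function(object) object@pools)

setMethod("show", "CofactorSpec", function(object) {
  cat("CofactorSpec with pools:\n")
  for (nm in names(object@pools))
    cat(sprintf("  %s: %s / %s\n", nm, object@pools[[nm]][["ox"]],
                object@pools[[nm]][["red"]]))
})

## TcosaModel delegation and own slots ---------------------------------------

#' @describeIn TcosaModel-class metabolite table of the expanded model.
#' @param object,x an object of the documented class.
#' @export
setMethod("metabolites", "TcosaModel", function(object, ...) metabolites(object@model))
#' @describeIn TcosaModel-class reaction table of the expanded model.
#' @export
setMethod("reactions", "TcosaModel", function(object, ...) reactions(object@model))
#' @describeIn TcosaModel-class stoichiometry of the expanded model.
#' @param reaction a reaction id or `NULL`.
#' @export
setMethod("stoichiometry", "TcosaModel", function(object, reaction = NULL, ...)
  stoichiometry(object@model, reaction = reaction))
#' @describeIn TcosaModel-class flux bounds of the expanded model.
#' @export
setMethod("fluxBounds", "TcosaModel", function(object, ...) fluxBounds(object@model))
#' @describeIn TcosaModel-class objective reaction id.
#' @export
setMethod("objectiveReaction", "TcosaModel", function(object) objectiveReaction(object@model))
#' @describeIn TcosaModel-class exchange reaction ids.
#' @export
setMethod("exchangeReactions", "TcosaModel", function(object) exchangeReactions(object@model))
#' @describeIn TcosaModel-class standard Gibbs energies.
#' @export
setMethod("dG0", "TcosaModel", function(object, ...) object@thermo@dG0)
#' @describeIn TcosaModel-class dG0 provenance tags.
#' @export
setMethod("dG0Tags", "TcosaModel", function(object, ...) object@thermo@dG0Tag)
#' @describeIn TcosaModel-class metabolite concentration bounds.
#' @export
setMethod("concentrationBounds", "TcosaModel", function(object, ...)
  concentrationBounds(object@thermo))
#' @describeIn TcosaModel-class cofactor pools.
#' @export
setMethod("cofactorPools", "TcosaModel", function(object) object@cofactors@pools)
#' @describeIn TcosaModel-class variant groups (original id -> derived ids).
#' @export
setMethod("variantGroups", "TcosaModel", function(object) object@variantGroups)
#' @describeIn TcosaModel-class provenance of every derived reaction.
#' @export
setMethod("provenance", "TcosaModel", function(object) object@provenance)
#' @describeIn TcosaModel-class named logical thermodynamic-activity flag.
#' @export
setMethod("thermoActive", "TcosaModel", function(object) object@thermoActive)
#' @describeIn TcosaModel-class reactions using two pools simultaneously.
#' @export
setMethod("dualCofactorReactions", "TcosaModel", function(object) object@dualCofactorReactions)

setMethod("show", "TcosaModel", function(object) {
  m <- object@model
  ng <- sum(vapply(object@variantGroups, length, 0L) >= 2L)
  cat(sprintf("TcosaModel: %d irreversible reactions, %d metabolites\n",
              length(m@rxnId), length(m@metId)))
  cat(sprintf("  %d variant groups with >= 2 members; %d dual-cofactor reactions\n",
              ng, length(object@dualCofactorReactions)))
  cat(sprintf("  pools: %s; %d thermo-active reactions\n",
              paste(names(object@cofactors@pools), collapse = ", "),
              sum(object@thermoActive)))
})

## MdfSolution ---------------------------------------------------------------

#' @describeIn MdfSolution-class the optimized MDF value B (kJ/mol).
#' @param object,x an object of the documented class.
#' @export
setMethod("mdfValue", "MdfSolution", function(object) object@B)
#' @describeIn MdfSolution-class the SubMDF value (or NA if not applicable).
#' @export
setMethod("subMdfValue", "MdfSolution", function(object)
  if (length(object@BSub)) object@BSub else NA_real_)
#' @describeIn MdfSolution-class flux vector of the solution.
#' @export
setMethod("fluxes", "MdfSolution", function(object) object@fluxes)
#' @describeIn MdfSolution-class logarithmized metabolite concentrations.
#' @export
setMethod("logConcentrations", "MdfSolution", function(object) object@logConc)
#' @describeIn MdfSolution-class per-reaction driving forces (kJ/mol).
#' @export
setMethod("drivingForces", "MdfSolution", function(object) object@drivingForces)
#' @describeIn MdfSolution-class solver status string.
#' @export
setMethod("solutionStatus", "MdfSolution", function(object) object@status)
#' @describeIn MdfSolution-class reactions carrying flux above the threshold.
#' @export
setMethod("activeReactions", "MdfSolution", function(object) object@activeSet)

setMethod("show", "MdfSolution", function(object) {
  cat(sprintf("MdfSolution (%s): status %s\n", object@objective, object@status))
  if (identical(object@status, "optimal")) {
    cat(sprintf("  B = %.4f kJ/mol", object@B))
    if (length(object@BSub)) cat(sprintf("; B_sub = %.4f kJ/mol", object@BSub))
    cat(sprintf("\n  %d active reactions\n", length(object@activeSet)))
  }
})

#' @describeIn SpecificityAssignment-class per-reaction pool choices.
#' @param object,x an object of the documented class.
#' @export
setMethod("specificityChoices", "SpecificityAssignment", function(object) object@choices)

setMethod("show", "SpecificityAssignment", function(object) {
  tb <- table(object@choices)
  cat(sprintf("SpecificityAssignment (%s): %s\n", object@scenario,
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
})

#' @describeIn RatioRange-class named vector with elements `ratioMin`,
#'   `ratioMax`, `rhoMin`, `rhoMax`.
#' @param object,x an object of the documented class.
#' @export
setMethod("ratioBounds", "RatioRange", function(object) {
  c(ratioMin = object@ratioMin, ratioMax = object@ratioMax,
    rhoMin = object@rhoMin, rhoMax = object@rhoMax)
})

setMethod("show", "RatioRange", function(object) {
  cat(sprintf("RatioRange (%s at B = %.4f, growth %.3f h^-1):\n",
              object@objective, object@fixedObjective, object@growth))
  cat(sprintf("  ratio in [%.4g, %.4g] (rho in [%.4f, %.4f])\n",
              object@ratioMin, object@ratioMax, object@rhoMin, object@rhoMax))
})
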