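## Generics for the accessor surface.

#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))
#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))
#' @export
setGeneric("stoichiometry", function(object, ...) standardGeneric("stoichiometry"))
#' @export
setGeneric("fluxBounds", function(object, ...) standardGeneric("fluxBounds"))
#' @export
setGeneric("objectiveReaction", function(object) standardGeneric("objectiveReaction"))
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))
#' @export
setGeneric("dG0", function(object, ...) standardGeneric("dG0"))
#' @export
setGeneric("dG0Tags", function(object, ...) standardGeneric("dG0Tags"))
#' @export
setGeneric("concentrationBounds", function(object, ...) standardGeneric("concentrationBounds"))
#' @export
setGeneric("cofactorPools", function(object) standardGeneric("cofactorPools"))
#' @export
setGeneric("variantGroups", function(object) standardGeneric("variantGroups"))
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @export
setGeneric("thermoActive", function(object) standardGeneric("thermoActive"))
#' @export
setGeneric("dualCofactorReactions", function(object) standardGeneric("dualCofactorReactions"))
#' @export
setGeneric("mdfValue", function(object) standardGeneric("mdfValue"))
#' @export
setGeneric("subMdfValue", function(object) standardGeneric("subMdfValue"))
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @export
setGeneric("logConcentrations", function(object) standardGeneric("logConcentrations"))
#' @export
setGeneric("drivingForces", function(object) standardGeneric("drivingForces"))
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))
#' @export
setGeneric("activeReactions", function(object) standardGeneric("activeReactions"))
#' @export
setGeneric("specificityChoices", function(object) standardGeneric("specificityChoices"))
#' @export
setGeneric("ratioBounds", function(object) standardGeneric("ratioBounds"))
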