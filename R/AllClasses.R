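#' @import methods
NULL

## ---------------------------------------------------------------------------
## MetabolicModel
## ---------------------------------------------------------------------------

#' Stoichiometric metabolic model
#'
#' An S4 container for a constraint-based metabolic model: metabolites (with an
#' internal/external flag), reactions as sparse stoichiometry maps, flux bounds
#' in mmol gDW^-1 h^-1, a growth/objective pseudo-reaction and the set of
#' exchange pseudo-reactions.
#'
#' @slot metId character vector of metabolite identifiers.
#' @slot metExternal logical vector, parallel to `metId`; external metabolites
#'   are exempt from the steady-state mass balance.
#' @slot metCompartment character vector of compartment labels.
#' @slot rxnId character vector of reaction identifiers.
#' @slot stoich named list (per reaction) of named numeric coefficient vectors;
#'   negative coefficients are substrates, positive are products.
#' @slot lb,ub numeric flux bounds per reaction.
#' @slot reversible logical per reaction.
#' @slot objectiveReaction id of the growth/objective pseudo-reaction.
#' @slot exchangeReactions ids of exchange (boundary) pseudo-reactions.
#'
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(
    metId = "character",
    metExternal = "logical",
    metCompartment = "character",
    rxnId = "character",
    stoich = "list",
    lb = "numeric",
    ub = "numeric",
    reversible = "logical",
    objectiveReaction = "character",
    exchangeReactions = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  nm <- length(object@metId)
  nr <- length(object@rxnId)
  if (length(object@metExternal) != nm || length(object@metCompartment) != nm)
    msgs <- c(msgs, "metabolite slots have inconsistent lengths")
  if (anyDuplicated(object@metId)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(object@rxnId)) msgs <- c(msgs, "duplicated reaction ids")
  if (length(object@stoich) != nr || length(object@lb) != nr ||
      length(object@ub) != nr || length(object@reversible) != nr)
    msgs <- c(msgs, "reaction slots have inconsistent lengths")
  bad <- which(object@lb > object@ub)
  if (length(bad))
    msgs <- c(msgs, sprintf("lower bound exceeds upper bound for reaction(s): %s",
                            paste(object@rxnId[bad], collapse = ", ")))
  for (i in seq_len(nr)) {
    s <- object@stoich[[i]]
    if (!length(s)) {
      msgs <- c(msgs, sprintf("reaction '%s' has empty stoichiometry", object@rxnId[i]))
      next
    }
    if (any(!is.finite(s)) || any(s == 0))
      msgs <- c(msgs, sprintf("reaction '%s' has a non-finite or zero coefficient",
                              object@rxnId[i]))
    unknown <- setdiff(names(s), object@metId)
    if (length(unknown))
      msgs <- c(msgs, sprintf("reaction '%s' references unknown metabolite(s): %s",
                              object@rxnId[i], paste(unknown, collapse = ", ")))
  }
  if (length(object@objectiveReaction) != 1L ||
      !(object@objectiveReaction %in% object@rxnId))
    msgs <- c(msgs, "objectiveReaction is not a reaction of the model")
  if (length(setdiff(object@exchangeReactions, object@rxnId)))
    msgs <- c(msgs, "exchangeReactions contains unknown reaction ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MetabolicModel
#'
#' @param metabolites data.frame with columns `id`, `external` (logical) and
#'   optionally `compartment`.
#' @param reactions named list: per reaction a list with elements `stoich`
#'   (named numeric), `lb`, `ub` and optionally `reversible` (defaults to
#'   `lb < 0`).
#' @param objective id of the growth/objective reaction.
#' @param exchanges character vector of exchange reaction ids; if `NULL`,
#'   single-metabolite boundary reactions are auto-detected.
#' @return a validated [MetabolicModel-class] object.
#' @export
metabolicModel <- function(metabolites, reactions, objective, exchanges = NULL) {
  stopifnot(is.data.frame(metabolites), all(c("id", "external") %in% names(metabolites)))
  comp <- if ("compartment" %in% names(metabolites)) as.character(metabolites$compartment)
          else rep("c", nrow(metabolites))
  rid <- names(reactions)
  if (is.null(rid)) stop("'reactions' must be a named list")
  stoich <- lapply(reactions, function(r) {
    s <- r$stoich
    storage.mode(s) <- "double"
    s[s != 0]
  })
  lb <- vapply(reactions, function(r) as.numeric(r$lb %||% 0), 0)
  ub <- vapply(reactions, function(r) as.numeric(r$ub %||% 1000), 0)
  rev <- vapply(reactions, function(r) isTRUE(r$reversible) || (is.null(r$reversible) && r$lb < 0), NA)
  names(stoich) <- names(lb) <- names(ub) <- names(rev) <- rid
  if (is.null(exchanges))
    exchanges <- rid[vapply(stoich, function(s) length(s) == 1L, NA)]
  new("MetabolicModel",
      metId = as.character(metabolites$id),
      metExternal = as.logical(metabolites$external),
      metCompartment = comp,
      rxnId = rid, stoich = stoich, lb = lb, ub = ub, reversible = rev,
      objectiveReaction = objective, exchangeReactions = exchanges)
}

## ---------------------------------------------------------------------------
## ThermoAnnotation
## ---------------------------------------------------------------------------

#' Thermodynamic annotation of a metabolic model
#'
#' Standard Gibbs free energies of reaction (kJ/mol) with provenance tags,
#' metabolite concentration bounds (molar), temperature and the set of species
#' whose concentration is pinned to 1 M (typically protons and water, whose
#' contributions are already folded into the transformed Gibbs energies).
#'
#' @slot dG0 named numeric; entries exist only for reactions with a value.
#' @slot dG0Tag named character; one of `computed`, `default_sentinel`,
#'   `median_imputed`, `relaxed`, `unconstrained` per annotated reaction.
#' @slot cMin,cMax named numeric molar concentration bounds per metabolite.
#' @slot temperature numeric, Kelvin.
#' @slot fixedUnitSpecies character; metabolites fixed at 1 M.
#' @slot metadata list of free-form provenance (e.g. the settings under which
#'   the Gibbs energies were estimated).
#' @exportClass ThermoAnnotation
setClass("ThermoAnnotation",
  representation(
    dG0 = "numeric",
    dG0Tag = "character",
    cMin = "numeric",
    cMax = "numeric",
    temperature = "numeric",
    fixedUnitSpecies = "character",
    metadata = "list"
  ),
  prototype(temperature = DEFAULT_TEMPERATURE_K, metadata = list())
)

setValidity("ThermoAnnotation", function(object) {
  msgs <- character(0)
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msgs <- c(msgs, "temperature must be a single positive value (K)")
  if (any(object@cMin <= 0) || any(object@cMax < object@cMin))
    msgs <- c(msgs, "concentration bounds must satisfy 0 < cMin <= cMax")
  if (!setequal(names(object@cMin), names(object@cMax)))
    msgs <- c(msgs, "cMin and cMax must cover the same metabolites")
  fx <- intersect(object@fixedUnitSpecies, names(object@cMin))
  if (length(fx) && (any(object@cMin[fx] != 1) || any(object@cMax[fx] != 1)))
    msgs <- c(msgs, "fixed-unit species must have cMin = cMax = 1")
  if (length(object@dG0Tag)) {
    if (!all(object@dG0Tag %in% DG_SOURCE_TAGS))
      msgs <- c(msgs, "unknown dG0 source tag")
    unc <- names(object@dG0Tag)[object@dG0Tag == "unconstrained"]
    if (length(intersect(unc, names(object@dG0))))
      msgs <- c(msgs, "reactions tagged 'unconstrained' must not carry a dG0")
  }
  if (any(!is.finite(object@dG0)))
    msgs <- c(msgs, "dG0 entries must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ThermoAnnotation
#'
#' @param dG0 named numeric vector of standard reaction Gibbs energies (kJ/mol).
#' @param dG0Tag named character vector of provenance tags; defaults to
#'   `computed` for every `dG0` entry.
#' @param cMin,cMax named numeric metabolite concentration bounds (M).
#' @param temperature temperature in Kelvin.
#' @param fixedUnitSpecies metabolites pinned to 1 M.
#' @param metadata free-form provenance list.
#' @return a validated [ThermoAnnotation-class].
#' @export
thermoAnnotation <- function(dG0 = numeric(0), dG0Tag = NULL,
                             cMin = numeric(0), cMax = numeric(0),
                             temperature = DEFAULT_TEMPERATURE_K,
                             fixedUnitSpecies = character(0),
                             metadata = list()) {
  if (is.null(dG0Tag)) {
    dG0Tag <- rep("computed", length(dG0))
    names(dG0Tag) <- names(dG0)
  }
  new("ThermoAnnotation", dG0 = dG0, dG0Tag = dG0Tag, cMin = cMin, cMax = cMax,
      temperature = temperature, fixedUnitSpecies = fixedUnitSpecies,
      metadata = metadata)
}

## ---------------------------------------------------------------------------
## CofactorSpec
## ---------------------------------------------------------------------------

#' Redox cofactor pool specification
#'
#' Names the oxidized/reduced metabolite pair of each redox cofactor pool,
#' e.g. `NAD -> (nad_c, nadh_c)` and `NADP -> (nadp_c, nadph_c)`, optionally a
#' hypothetical third pool `NADZ -> (nadz_c, nadzh_c)`.
#'
#' @slot pools named list; each element a named character vector with elements
#'   `ox` and `red`.
#' @exportClass CofactorSpec
setClass("CofactorSpec", representation(pools = "list"))

setValidity("CofactorSpec", function(object) {
  msgs <- character(0)
  if (!length(object@pools)) msgs <- c(msgs, "at least one cofactor pool must be defined")
  if (is.null(names(object@pools)) || anyDuplicated(names(object@pools)))
    msgs <- c(msgs, "pools must be uniquely named")
  ids <- unlist(lapply(object@pools, function(p) p[c("ox", "red")]), use.names = FALSE)
  if (any(is.na(ids))) msgs <- c(msgs, "each pool needs 'ox' and 'red' metabolite ids")
  if (anyDuplicated(ids)) msgs <- c(msgs, "cofactor metabolite ids must be distinct")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CofactorSpec
#'
#' @param ... named pool definitions, each a character vector with elements
#'   `ox` and `red` (BiGG-style defaults are used by [defaultCofactors()]).
#' @return a validated [CofactorSpec-class].
#' @export
cofactorSpec <- function(...) {
  pools <- lapply(list(...), function(p) p[c("ox", "red")])
  new("CofactorSpec", pools = pools)
}

#' Default NAD/NADP cofactor pools with BiGG metabolite ids
#'
#' @param nadz if `TRUE`, adds the hypothetical third pool
#'   `NADZ -> (nadz_c, nadzh_c)`.
#' @return a [CofactorSpec-class].
#' @export
defaultCofactors <- function(nadz = FALSE) {
  if (nadz)
    cofactorSpec(NAD = c(ox = "nad_c", red = "nadh_c"),
                 NADP = c(ox = "nadp_c", red = "nadph_c"),
                 NADZ = c(ox = "nadz_c", red = "nadzh_c"))
  else
    cofactorSpec(NAD = c(ox = "nad_c", red = "nadh_c"),
                 NADP = c(ox = "nadp_c", red = "nadph_c"))
}

## ---------------------------------------------------------------------------
## TcosaModel
## ---------------------------------------------------------------------------

#' Cofactor-expanded irreversible model
#'
#' The result of the full reconfiguration pipeline: an irreversible
#' [MetabolicModel-class] in which every redox reaction carries one copy per
#' cofactor pool, together with its [ThermoAnnotation-class], the cofactor
#' pools, variant groups (original reaction id -> derived reaction ids, at most
#' one of which may be active), per-derived-reaction provenance, the
#' thermodynamic-activity flag, and the reactions using two pools
#' simultaneously (never duplicated).
#'
#' @slot model irreversible [MetabolicModel-class].
#' @slot thermo [ThermoAnnotation-class].
#' @slot cofactors [CofactorSpec-class].
#' @slot variantGroups named list: original id -> character vector of derived ids.
#' @slot provenance data.frame with columns `id`, `original`, `direction`
#'   (`FWD`/`REV`/`NA`), `pool` (pool tag or `NA`), `role`
#'   (`ORIGINAL`/`VARIANT`/`NA`).
#' @slot thermoActive named logical; `FALSE` for exchange/growth pseudo-reactions
#'   and relaxed reactions.
#' @slot dualCofactorReactions character.
#' @exportClass TcosaModel
setClass("TcosaModel",
  representation(
    model = "MetabolicModel",
    thermo = "ThermoAnnotation",
    cofactors = "CofactorSpec",
    variantGroups = "list",
    provenance = "data.frame",
    thermoActive = "logical",
    dualCofactorReactions = "character"
  )
)

setValidity("TcosaModel", function(object) {
  msgs <- character(0)
  m <- object@model
  if (any(m@lb < 0))
    msgs <- c(msgs, "TcosaModel reactions must all be irreversible (lb >= 0)")
  if (!identical(sort(names(object@thermoActive)), sort(m@rxnId)))
    msgs <- c(msgs, "thermoActive must cover exactly the model's reactions")
  der <- unlist(object@variantGroups, use.names = FALSE)
  if (length(setdiff(der, m@rxnId)))
    msgs <- c(msgs, "variantGroups reference unknown reactions")
  prov <- object@provenance
  need <- c("id", "original", "direction", "pool", "role")
  if (!all(need %in% names(prov)))
    msgs <- c(msgs, "provenance must have columns id/original/direction/pool/role")
  dup <- intersect(object@dualCofactorReactions, prov$id[!is.na(prov$role) & prov$role == "VARIANT"])
  if (length(dup))
    msgs <- c(msgs, "dual-cofactor reactions must not have cofactor variants")
  ## dG antisymmetry of split pairs (computed entries); sentinel pairs equal
  tags <- object@thermo@dG0Tag
  dg <- object@thermo@dG0
  if (all(need %in% names(prov))) {
    sp <- prov[!is.na(prov$direction), , drop = FALSE]
    if (nrow(sp)) {
      key <- paste(sp$original, ifelse(is.na(sp$pool), "", sp$pool), ifelse(is.na(sp$role), "", sp$role))
      for (k in unique(key)) {
        pair <- sp$id[key == k]
        if (length(pair) != 2L) next
        if (!all(pair %in% names(dg))) next
        tg <- tags[pair]
        if (all(tg == "computed") && abs(sum(dg[pair])) > 1e-9)
          msgs <- c(msgs, sprintf("split pair of '%s' violates dG0 antisymmetry", k))
        if (all(tg == "default_sentinel") && abs(diff(dg[pair])) > 1e-9)
          msgs <- c(msgs, sprintf("sentinel split pair of '%s' must share one dG0", k))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## MilpConfig
## ---------------------------------------------------------------------------

#' Solver configuration for the driving-force MILPs
#'
#' @slot bigM numeric; length 0 means "auto" (a certified bound above the
#'   maximal attainable driving force is computed from the instance), otherwise
#'   a fixed value in kJ/mol.
#' @slot solver backend name (currently `"highs"`).
#' @slot feasTol,intTol requested solver tolerances.
#' @slot epsActive flux threshold above which a reaction counts as active.
#' @slot bMin feasibility floor used by SubMDF-type analyses (kJ/mol).
#' @exportClass MilpConfig
setClass("MilpConfig",
  representation(bigM = "numeric", solver = "character",
                 feasTol = "numeric", intTol = "numeric",
                 epsActive = "numeric", bMin = "numeric"),
  prototype(bigM = numeric(0), solver = "highs", feasTol = 1e-9, intTol = 1e-9,
            epsActive = ACTIVE_FLUX_EPS, bMin = 0.1)
)

setValidity("MilpConfig", function(object) {
  msgs <- character(0)
  if (length(object@bigM) > 1L || (length(object@bigM) == 1L && object@bigM <= 0))
    msgs <- c(msgs, "bigM must be empty (auto) or a single positive value")
  if (object@epsActive <= 0) msgs <- c(msgs, "epsActive must be > 0")
  if (object@bMin <= 0) msgs <- c(msgs, "bMin must be > 0")
  if (length(msgs)) msgs else TRUE
}
)

#' Construct a MilpConfig
#'
#' @param bigM `"auto"` or a fixed positive value in kJ/mol.
#' @param solver backend name; `"highs"` is the shipped backend.
#' @param feasTol,intTol requested feasibility/integrality tolerances.
#' @param epsActive active-flux threshold (mmol gDW^-1 h^-1).
#' @param bMin SubMDF feasibility floor (kJ/mol), default 0.1.
#' @return a [MilpConfig-class].
#' @export
milpConfig <- function(bigM = "auto", solver = "highs", feasTol = 1e-9,
                       intTol = 1e-9, epsActive = ACTIVE_FLUX_EPS, bMin = 0.1) {
  bm <- if (identical(bigM, "auto")) numeric(0) else as.numeric(bigM)
  new("MilpConfig", bigM = bm, solver = solver, feasTol = feasTol,
      intTol = intTol, epsActive = epsActive, bMin = bMin)
}

## ---------------------------------------------------------------------------
## MdfSolution
## ---------------------------------------------------------------------------

#' Solution of a driving-force optimization
#'
#' @slot B max-min driving force (kJ/mol); negative values measure the distance
#'   from thermodynamic feasibility.
#' @slot BSub SubMDF value (length 0 unless a subnetwork objective was used).
#' @slot fluxes,logConc,z,drivingForces named numeric solution vectors
#'   (driving forces only for thermo-active reactions).
#' @slot status solver status: `optimal`, `infeasible`, `unbounded` or `error`.
#' @slot activeSet reactions with flux above the active threshold.
#' @slot objective label of the optimized quantity.
#' @exportClass MdfSolution
setClass("MdfSolution",
  representation(B = "numeric", BSub = "numeric", fluxes = "numeric",
                 logConc = "numeric", z = "numeric", drivingForces = "numeric",
                 status = "character", activeSet = "character",
                 objective = "character"),
  prototype(B = NA_real_, BSub = numeric(0), status = "error",
            objective = "MDF")
)

## ---------------------------------------------------------------------------
## SpecificityAssignment
## ---------------------------------------------------------------------------

#' Cofactor-specificity assignment for a scenario
#'
#' @slot choices named character: per original redox reaction one of the pool
#'   names (e.g. `NAD`, `NADP`, `NADZ`), `flexible`, or `blocked`.
#' @slot scenario one of `wild_type`, `single_pool`, `flexible`, `random`.
#' @slot seed integer RNG seed for random scenarios (NA otherwise).
#' @slot poolMode `free` or `fixed` pool size for random scenarios.
#' @exportClass SpecificityAssignment
setClass("SpecificityAssignment",
  representation(choices = "character", scenario = "character",
                 seed = "integer", poolMode = "character"),
  prototype(seed = NA_integer_, poolMode = NA_character_)
)

setValidity("SpecificityAssignment", function(object) {
  if (!(object@scenario %in% c("wild_type", "single_pool", "flexible", "random")))
    return("unknown scenario label")
  TRUE
})

## ---------------------------------------------------------------------------
## RatioRange
## ---------------------------------------------------------------------------

#' Feasible range of the cofactor reduction-ratio quotient
#'
#' Extremes of `rho = ln((red1/ox1)/(red2/ox2))` (by default the NADH/NAD+
#' over NADPH/NADP+ quotient) at a fixed optimal MDF or SubMDF.
#'
#' @slot rhoMin,rhoMax log-scale extremes.
#' @slot ratioMin,ratioMax exponentiated extremes.
#' @slot fixedObjective the (Sub)MDF value the range was computed at.
#' @slot objective `"MDF"` or `"SubMDF"`.
#' @slot growth growth set point (h^-1).
#' @exportClass RatioRange
setClass("RatioRange",
  representation(rhoMin = "numeric", rhoMax = "numeric", ratioMin = "numeric",
                 ratioMax = "numeric", fixedObjective = "numeric",
                 objective = "character", growth = "numeric")
)

setValidity("RatioRange", function(object) {
  if (length(object@rhoMin) && length(object@rhoMax) &&
      object@rhoMin > object@rhoMax + 1e-9)
    return("rhoMin must not exceed rhoMax")
  TRUE
})
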