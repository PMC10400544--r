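## Model reconfiguration: reversible splitting, cofactor duplication /
## triplication, and the full preparation pipeline.

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' Every reversible reaction `R` with bounds `[a, b]`, `a < 0`, is replaced by
#' `R_FWD` (unchanged stoichiometry, bounds `[0, b]`) and `R_REV` (negated
#' stoichiometry, bounds `[0, -a]`). Standard Gibbs energies are negated for
#' the backward copy, except sentinel-tagged entries, which keep the sentinel
#' in both directions so that neither direction is favored.
#'
#' @param model a [MetabolicModel-class].
#' @param thermo a [ThermoAnnotation-class].
#' @return list with the split `model`, the updated `thermo`, and a
#'   `provenance` data.frame (`id`, `original`, `direction`).
#' @export
splitReversible <- function(model, thermo) {
  ids <- character(0); stoich <- list(); lb <- ub <- numeric(0)
  prov <- list()
  dg <- thermo@dG0; tags <- thermo@dG0Tag
  newDg <- numeric(0); newTags <- character(0)
  carry <- function(from, to, negate = FALSE) {
    if (from %in% names(tags)) newTags[to] <<- tags[[from]]
    if (from %in% names(dg)) {
      v <- dg[[from]]
      if (negate && !identical(tags[[from]], "default_sentinel")) v <- -v
      newDg[to] <<- v
    }
  }
  exch <- model@exchangeReactions
  obj <- model@objectiveReaction
  for (j in seq_along(model@rxnId)) {
    id <- model@rxnId[j]
    s <- model@stoich[[j]]
    if (model@reversible[j] && model@lb[j] < 0) {
      fid <- paste0(id, "_FWD"); rid <- paste0(id, "_REV")
      ids <- c(ids, fid, rid)
      stoich[[fid]] <- s; stoich[[rid]] <- -s
      lb <- c(lb, 0, 0); ub <- c(ub, max(model@ub[j], 0), -model@lb[j])
      carry(id, fid); carry(id, rid, negate = TRUE)
      prov[[length(prov) + 1L]] <- data.frame(id = c(fid, rid), original = id,
                                              direction = c("FWD", "REV"),
                                              stringsAsFactors = FALSE)
      if (id %in% exch) exch <- c(setdiff(exch, id), fid, rid)
      if (id == obj) obj <- fid
    } else {
      ids <- c(ids, id)
      stoich[[id]] <- s
      lb <- c(lb, max(model@lb[j], 0)); ub <- c(ub, model@ub[j])
      carry(id, id)
      prov[[length(prov) + 1L]] <- data.frame(id = id, original = id,
                                              direction = NA_character_,
                                              stringsAsFactors = FALSE)
    }
  }
  names(lb) <- names(ub) <- ids
  rev <- stats::setNames(rep(FALSE, length(ids)), ids)
  splitModel <- new("MetabolicModel",
    metId = model@metId, metExternal = model@metExternal,
    metCompartment = model@metCompartment,
    rxnId = ids, stoich = stoich, lb = lb, ub = ub, reversible = rev,
    objectiveReaction = obj, exchangeReactions = exch)
  splitThermo <- methods::initialize(thermo, dG0 = newDg, dG0Tag = newTags)
  list(model = splitModel, thermo = splitThermo,
       provenance = do.call(rbind, prov))
}

## Shared expansion engine behind duplication and triplication. `dGAdjust` is
## a named per-pool Gibbs-energy shift (kJ/mol per unit of reduced-cofactor
## stoichiometry) applied to variants of that pool.
expandRedoxVariants <- function(model, thermo, cofactors, dGAdjust,
                                provenance = NULL, thermoActive = NULL) {
  if (any(model@lb < 0))
    stop("model must be split to irreversible before cofactor expansion")
  pools <- cofactors@pools
  poolNames <- names(pools)
  if (is.null(provenance))
    provenance <- data.frame(id = model@rxnId, original = model@rxnId,
                             direction = NA_character_, stringsAsFactors = FALSE)
  origOf <- stats::setNames(provenance$original, provenance$id)
  dirOf <- stats::setNames(provenance$direction, provenance$id)

  dg <- thermo@dG0; tags <- thermo@dG0Tag
  ids <- character(0); stoich <- list(); lb <- ub <- numeric(0)
  newDg <- numeric(0); newTags <- character(0)
  prov <- list()
  dual <- character(0)
  taFlags <- c()

  baseTa <- function(id) {
    if (!is.null(thermoActive) && id %in% names(thermoActive))
      return(isTRUE(thermoActive[[id]]))
    tag <- if (id %in% names(tags)) tags[[id]] else NA_character_
    !(identical(tag, "unconstrained") ||
        id %in% model@exchangeReactions || id == model@objectiveReaction)
  }

  for (j in seq_along(model@rxnId)) {
    id <- model@rxnId[j]
    st <- model@stoich[[j]]
    present <- vapply(pools, function(p) any(p[c("ox", "red")] %in% names(st)), NA)
    complete <- vapply(pools, function(p) all(p[c("ox", "red")] %in% names(st)), NA)
    isDual <- sum(present) >= 2L
    if (isDual) dual <- c(dual, id)
    ## the growth/objective pseudo-reaction is never duplicated, even when it
    ## touches only one pool
    if (!isDual && sum(complete) == 1L && id != model@objectiveReaction) {
      p <- poolNames[which(complete)]
      dirTok <- if (!is.na(dirOf[[id]])) paste0("_", dirOf[[id]]) else ""
      base <- origOf[[id]]
      mkId <- function(role, pool) paste0(base, dirTok, "_", role, "_", pool, "_TCOSA")
      for (q in poolNames) {
        role <- if (q == p) "ORIGINAL" else "VARIANT"
        nid <- mkId(role, q)
        s2 <- st
        if (q != p) {
          missingMet <- setdiff(pools[[q]][c("ox", "red")], model@metId)
          if (length(missingMet))
            stop("configuration error: cofactor metabolite(s) absent from model: ",
                 paste(missingMet, collapse = ", "))
          nm <- names(s2)
          nm[nm == pools[[p]][["ox"]]] <- pools[[q]][["ox"]]
          nm[nm == pools[[p]][["red"]]] <- pools[[q]][["red"]]
          names(s2) <- nm
        }
        ids <- c(ids, nid)
        stoich[[nid]] <- s2
        lb <- c(lb, model@lb[[j]]); ub <- c(ub, model@ub[[j]])
        if (id %in% names(dg)) {
          v <- dg[[id]]
          adj <- if (q %in% names(dGAdjust)) dGAdjust[[q]] else 0
          if (!is.na(adj) && adj != 0) {
            nuRed <- s2[[pools[[q]][["red"]]]]
            v <- v + adj * nuRed
          }
          newDg[nid] <- v
        }
        if (id %in% names(tags)) newTags[nid] <- tags[[id]]
        taFlags[nid] <- baseTa(id)
        prov[[length(prov) + 1L]] <- data.frame(
          id = nid, original = base, direction = dirOf[[id]], pool = q,
          role = role, stringsAsFactors = FALSE)
      }
    } else {
      ids <- c(ids, id)
      stoich[[id]] <- st
      lb <- c(lb, model@lb[[j]]); ub <- c(ub, model@ub[[j]])
      if (id %in% names(dg)) newDg[id] <- dg[[id]]
      if (id %in% names(tags)) newTags[id] <- tags[[id]]
      taFlags[id] <- baseTa(id)
      prov[[length(prov) + 1L]] <- data.frame(
        id = id, original = origOf[[id]], direction = dirOf[[id]],
        pool = NA_character_, role = NA_character_, stringsAsFactors = FALSE)
    }
  }
  names(lb) <- names(ub) <- ids
  provDf <- do.call(rbind, prov)
  groups <- split(provDf$id, provDf$original)
  obj <- model@objectiveReaction
  if (!(obj %in% ids)) stop("objective reaction lost during expansion")
  exch <- intersect(model@exchangeReactions, ids)
  newModel <- new("MetabolicModel",
    metId = model@metId, metExternal = model@metExternal,
    metCompartment = model@metCompartment,
    rxnId = ids, stoich = stoich, lb = lb, ub = ub,
    reversible = stats::setNames(rep(FALSE, length(ids)), ids),
    objectiveReaction = obj, exchangeReactions = exch)
  newThermo <- methods::initialize(thermo, dG0 = newDg, dG0Tag = newTags)
  new("TcosaModel", model = newModel, thermo = newThermo, cofactors = cofactors,
      variantGroups = groups, provenance = provDf,
      thermoActive = stats::setNames(as.logical(taFlags), ids),
      dualCofactorReactions = dual)
}

#' Duplicate redox reactions with swapped cofactor specificity
#'
#' Every irreversible reaction using exactly one cofactor pool (both its
#' oxidized and reduced species) is renamed `<ID>_ORIGINAL_<pool>_TCOSA` and
#' gains a duplicate `<ID>_VARIANT_<otherpool>_TCOSA` in which the oxidized
#' and reduced cofactor species are substituted at identical stoichiometric
#' coefficients, bounds and standard Gibbs energy (the two couples share the
#' same standard redox potential). Reactions touching both pools
#' simultaneously (transhydrogenase-, NAD-kinase- and biomass-like) are
#' recorded as dual-cofactor reactions and never duplicated. Variant groups
#' collect, per original (pre-split) reaction, all derived copies — up to four
#' for a reversible redox reaction — of which at most one may be active in any
#' driving-force solution.
#'
#' @param model an irreversible [MetabolicModel-class] (after
#'   [splitReversible()]).
#' @param thermo the matching [ThermoAnnotation-class].
#' @param cofactors a two-pool [CofactorSpec-class].
#' @param provenance the `provenance` table returned by [splitReversible()]
#'   (optional; identity mapping when missing).
#' @param thermoActive optional named logical overriding the derived
#'   thermodynamic-activity flags.
#' @return a [TcosaModel-class].
#' @export
duplicateRedoxReactions <- function(model, thermo, cofactors = defaultCofactors(),
                                    provenance = NULL, thermoActive = NULL) {
  if (length(cofactors@pools) != 2L)
    stop("configuration error: duplication requires exactly two cofactor pools")
  adj <- stats::setNames(c(0, 0), names(cofactors@pools))
  expandRedoxVariants(model, thermo, cofactors, adj, provenance, thermoActive)
}

#' Triplicate redox reactions with a hypothetical third cofactor pool
#'
#' As [duplicateRedoxReactions()], but with a third variant per redox reaction
#' using a hypothetical cofactor couple whose standard redox potential differs
#' from NAD(P)H/NAD(P)+ by `dEShift_mV`. The standard Gibbs energy of each
#' third-pool variant is shifted by
#' `redoxPotentialToDGShift(dEShift_mV, nElectrons)` per unit stoichiometry of
#' the reduced cofactor: lowering the potential by 155 mV makes reduction
#' harder and raises the variant's Gibbs energy by ~30 kJ/mol per cofactor.
#' The third pool's metabolites are added to the model when absent, with the
#' concentration bounds of the first pool.
#'
#' @inheritParams duplicateRedoxReactions
#' @param cofactors a three-pool [CofactorSpec-class] (see
#'   [defaultCofactors()] with `nadz = TRUE`).
#' @param dEShift_mV redox-potential shift of the third pool in millivolts
#'   (negative = lower potential).
#' @param nElectrons electrons transferred by the couple (2 for NAD-like).
#' @return a [TcosaModel-class] with up to three variants per redox reaction.
#' @export
triplicateRedoxReactions <- function(model, thermo, cofactors = defaultCofactors(nadz = TRUE),
                                     dEShift_mV = 0, nElectrons = 2,
                                     provenance = NULL, thermoActive = NULL) {
  if (length(cofactors@pools) != 3L)
    stop("configuration error: triplication requires exactly three cofactor pools")
  third <- if ("NADZ" %in% names(cofactors@pools)) "NADZ"
           else names(cofactors@pools)[3L]
  thirdMets <- cofactors@pools[[third]][c("ox", "red")]
  missingMet <- setdiff(thirdMets, model@metId)
  if (length(missingMet)) {
    model <- new("MetabolicModel",
      metId = c(model@metId, missingMet),
      metExternal = c(model@metExternal, rep(FALSE, length(missingMet))),
      metCompartment = c(model@metCompartment, rep("c", length(missingMet))),
      rxnId = model@rxnId, stoich = model@stoich, lb = model@lb, ub = model@ub,
      reversible = model@reversible, objectiveReaction = model@objectiveReaction,
      exchangeReactions = model@exchangeReactions)
    ref <- cofactors@pools[[1L]][c("ox", "red")]
    cMin <- thermo@cMin; cMax <- thermo@cMax
    for (i in seq_along(missingMet)) {
      src <- ref[[if (grepl("h$", missingMet[i])) "red" else "ox"]]
      cMin[missingMet[i]] <- if (src %in% names(cMin)) cMin[[src]] else DEFAULT_C_MIN
      cMax[missingMet[i]] <- if (src %in% names(cMax)) cMax[[src]] else DEFAULT_C_MAX
    }
    thermo <- methods::initialize(thermo, cMin = cMin, cMax = cMax)
  }
  adj <- stats::setNames(rep(0, 3), names(cofactors@pools))
  adj[third] <- redoxPotentialToDGShift(dEShift_mV, nElectrons)
  expandRedoxVariants(model, thermo, cofactors, adj, provenance, thermoActive)
}

#' Run the full reconfiguration pipeline
#'
#' Convenience wrapper: default Gibbs-energy assignment, per-species median
#' imputation for redox reactions, reversible splitting, and cofactor
#' duplication (or triplication when `cofactors` has three pools).
#'
#' @param model a [MetabolicModel-class].
#' @param thermo a [ThermoAnnotation-class] with the computed entries.
#' @param cofactors a [CofactorSpec-class].
#' @param sentinel sentinel Gibbs energy (kJ/mol) for unknown/transport
#'   reactions.
#' @param imputeMedians impute per-species medians for redox reactions
#'   lacking a computed value.
#' @param thermoActive optional named logical (pre-split reaction ids)
#'   overriding thermodynamic-activity flags.
#' @param dEShift_mV,nElectrons third-pool settings, see
#'   [triplicateRedoxReactions()].
#' @return a [TcosaModel-class].
#' @export
buildTcosaModel <- function(model, thermo, cofactors = defaultCofactors(),
                            sentinel = DEFAULT_DG_SENTINEL, imputeMedians = TRUE,
                            thermoActive = NULL, dEShift_mV = 0, nElectrons = 2) {
  thermo <- assignDefaultDG(model, thermo, sentinel = sentinel)
  if (imputeMedians) {
    can <- tryCatch({ imputeRedoxMedians(model, thermo, cofactors) },
                    error = function(e) NULL)
    if (!is.null(can)) thermo <- can
  }
  sp <- splitReversible(model, thermo)
  ta <- thermoActive
  if (!is.null(ta)) {
    ## propagate pre-split flags to split copies
    full <- stats::setNames(ta[sp$provenance$original], sp$provenance$id)
    ta <- full[!is.na(full)]
  }
  if (length(cofactors@pools) == 3L)
    triplicateRedoxReactions(sp$model, sp$thermo, cofactors,
                             dEShift_mV = dEShift_mV, nElectrons = nElectrons,
                             provenance = sp$provenance, thermoActive = ta)
  else
    duplicateRedoxReactions(sp$model, sp$thermo, cofactors,
                            provenance = sp$provenance, thermoActive = ta)
}
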