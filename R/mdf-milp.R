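## The driving-force MILPs. One flexible builder covers MDF, SubMDF, the
## census, ratio-variability and minimal-swap variants; thin exported wrappers
## construct, solve and post-process.

rtOf <- function(tc) GAS_CONSTANT_KJ * tc@thermo@temperature

## log-concentration bounds for every metabolite (defaults where unannotated,
## 0 for fixed-unit species).
logConcBounds <- function(tc) {
  m <- tc@model
  cMin <- stats::setNames(rep(DEFAULT_C_MIN, length(m@metId)), m@metId)
  cMax <- stats::setNames(rep(DEFAULT_C_MAX, length(m@metId)), m@metId)
  ann <- intersect(names(tc@thermo@cMin), m@metId)
  cMin[ann] <- tc@thermo@cMin[ann]
  cMax[ann] <- tc@thermo@cMax[ann]
  fx <- intersect(tc@thermo@fixedUnitSpecies, m@metId)
  cMin[fx] <- cMax[fx] <- 1
  list(lo = log(cMin), hi = log(cMax), fixed = fx)
}

## Reactions subject to the driving-force constraint.
thermoConstrained <- function(tc) {
  ids <- tc@model@rxnId
  ids[tc@thermoActive[ids] & ids %in% names(tc@thermo@dG0)]
}

## Certified driving-force envelope: per thermo-constrained reaction the
## extreme attainable f_i over the concentration box, plus bounds for the
## B/B_sub variables. The per-reaction deactivation constant in Eq.-7-type
## rows must cover B's upper bound minus the reaction's own minimum f, which
## a single global constant would not do for strongly endergonic reactions.
dfEnvelope <- function(tc, config = milpConfig()) {
  lc <- logConcBounds(tc)
  span <- pmax(abs(lc$lo), abs(lc$hi))
  span[lc$fixed] <- 0
  ids <- thermoConstrained(tc)
  rt <- rtOf(tc)
  if (!length(ids)) {
    bigM <- if (length(config@bigM)) config@bigM else 1
    return(list(fMax = numeric(0), fMin = numeric(0), bigM = bigM,
                Bub = bigM, Blb = -bigM, lc = lc, rt = rt))
  }
  fMax <- vapply(ids, function(id) {
    s <- tc@model@stoich[[id]]
    -tc@thermo@dG0[[id]] + rt * sum(abs(s) * span[names(s)])
  }, 0)
  fMin <- vapply(ids, function(id) {
    s <- tc@model@stoich[[id]]
    -tc@thermo@dG0[[id]] - rt * sum(abs(s) * span[names(s)])
  }, 0)
  bigM <- if (length(config@bigM)) config@bigM else max(fMax) + 1
  list(fMax = fMax, fMin = fMin, bigM = bigM,
       Bub = bigM, Blb = min(fMin) - 1, lc = lc, rt = rt)
}

#' Big-M bound for the driving-force constraints
#'
#' In `auto` mode returns
#' `max_i (-dG0_i + RT * sum_m |S_mi| * max(|ln cMin_m|, |ln cMax_m|)) + 1`
#' over all thermo-constrained reactions, a certified upper bound on any
#' attainable driving force; in fixed mode returns the configured value.
#'
#' @param tcosa a [TcosaModel-class].
#' @param config a [MilpConfig-class].
#' @return big-M value in kJ/mol.
#' @export
computeBigM <- function(tcosa, config = milpConfig()) {
  dfEnvelope(tcosa, config)$bigM
}

#' Driving force of a reaction at given log-concentrations
#'
#' `f_i = -dG0_i - RT * S[, i]' x`, using the extended stoichiometry
#' including external metabolites; fixed-unit species contribute zero.
#'
#' @param reactionId a thermo-active reaction with a standard Gibbs energy.
#' @param x named numeric vector of logarithmized molar concentrations.
#' @param tcosa a [TcosaModel-class].
#' @return driving force in kJ/mol.
#' @export
drivingForce <- function(reactionId, x, tcosa) {
  if (!(reactionId %in% tcosa@model@rxnId))
    stop("unknown reaction: ", reactionId)
  if (!isTRUE(tcosa@thermoActive[[reactionId]]) ||
      !(reactionId %in% names(tcosa@thermo@dG0)))
    stop("contract error: reaction '", reactionId,
         "' carries no driving-force constraint")
  s <- tcosa@model@stoich[[reactionId]]
  xs <- stats::setNames(rep(0, length(s)), names(s))
  known <- intersect(names(s), names(x))
  xs[known] <- x[known]
  xs[intersect(names(s), tcosa@thermo@fixedUnitSpecies)] <- 0
  -tcosa@thermo@dG0[[reactionId]] - rtOf(tcosa) * sum(s * xs)
}

## ---------------------------------------------------------------------------
## Problem builder
## ---------------------------------------------------------------------------

## constraints: list(growthMin =, fixedFluxes = named numeric, blocked =
## character, extra = list(list(rxns =, coefs =, ub =))) ; all optional.
##
## mode / options:
##   objective = "B" | "BSub" | list(vars=, coefs=, maximize=)
##   subset    = reaction ids for the SubMDF constraint set (NULL = none)
##   fixLevel  = list(kind = "B"|"BSub", value =, band =): demanded optimum
##   swapSet   = named numeric ub per swap-gated reaction (adds binaries)
buildDfProblem <- function(tc, constraints = list(), config = milpConfig(),
                           objective = "B", subset = NULL, fixLevel = NULL,
                           swapSet = NULL, relaxable = NULL) {
  m <- tc@model
  rxns <- m@rxnId
  mets <- m@metId
  env <- dfEnvelope(tc, config)
  lc <- env$lc
  bigM <- env$bigM
  rt <- env$rt
  thermoIds <- thermoConstrained(tc)
  useBSub <- !is.null(subset) || identical(objective, "BSub") ||
    (!is.null(fixLevel) && identical(fixLevel$kind, "BSub"))
  if (useBSub && is.null(subset))
    stop("a SubMDF-type problem needs a reaction subset")

  vn <- c(paste0("r_", rxns), paste0("x_", mets), paste0("z_", rxns), "B")
  if (useBSub) vn <- c(vn, "BSub")
  if (!is.null(swapSet)) vn <- c(vn, paste0("w_", names(swapSet)))
  if (!is.null(relaxable)) vn <- c(vn, paste0("u_", relaxable))
  p <- milpProblem(vn, maximize = TRUE)

  ## flux bounds (scenario blocking / demanded fluxes folded in)
  lb <- m@lb; ub <- m@ub
  if (!is.null(constraints$blocked)) {
    bl <- constraints$blocked
    lb[bl] <- 0; ub[bl] <- 0
  }
  if (!is.null(constraints$fixedFluxes)) {
    ff <- constraints$fixedFluxes
    lb[names(ff)] <- ff; ub[names(ff)] <- ff
  }
  if (!is.null(constraints$growthMin)) {
    g <- m@objectiveReaction
    lb[g] <- max(lb[g], constraints$growthMin)
  }
  if (!is.null(swapSet)) ub[names(swapSet)] <- swapSet
  p <- mpSetBounds(p, paste0("r_", rxns), lb = unname(lb), ub = unname(ub))
  p <- mpSetBounds(p, paste0("x_", mets), lb = unname(lc$lo[mets]),
                   ub = unname(lc$hi[mets]))
  if (length(lc$fixed))
    p <- mpSetBounds(p, paste0("x_", lc$fixed), lb = 0, ub = 0)
  p <- mpSetBinary(p, paste0("z_", rxns))
  p <- mpSetBounds(p, "B", lb = env$Blb, ub = env$Bub)
  if (useBSub) p <- mpSetBounds(p, "BSub", lb = env$Blb, ub = env$Bub)

  ## Steady-state mass balance over internal metabolites.
  internal <- mets[!m@metExternal]
  byMet <- stats::setNames(vector("list", length(internal)), internal)
  for (j in seq_along(rxns)) {
    s <- m@stoich[[j]]
    for (mm in intersect(names(s), internal))
      byMet[[mm]] <- c(byMet[[mm]], stats::setNames(s[[mm]], rxns[j]))
  }
  for (mm in internal) {
    row <- byMet[[mm]]
    if (is.null(row)) next
    p <- mpAddRow(p, paste0("r_", names(row)), unname(row), lb = 0, ub = 0)
  }

  ## Flux-indicator coupling r_i <= z_i * ub_i.
  for (id in rxns) {
    if (ub[[id]] <= 0) next
    p <- mpAddRow(p, c(paste0("r_", id), paste0("z_", id)), c(1, -ub[[id]]),
                  ub = 0)
  }

  ## Driving-force constraints: B + RT * S' x + M_i z_i <= -dG0_i + M_i,
  ## with the per-reaction constant M_i = B_ub - fMin_i + 1 certified to make
  ## the row vacuous at z_i = 0 (optionally also a relaxation binary u_i).
  for (id in thermoIds) {
    s <- tc@model@stoich[[id]]
    keep <- setdiff(names(s), lc$fixed)
    Mi <- max(env$Bub - env$fMin[[id]] + 1, 1)
    vars <- c("B", paste0("x_", keep), paste0("z_", id))
    coefs <- c(1, rt * unname(s[keep]), Mi)
    if (!is.null(relaxable) && id %in% relaxable) {
      vars <- c(vars, paste0("u_", id))
      coefs <- c(coefs, -Mi)
    }
    p <- mpAddRow(p, vars, coefs, ub = -tc@thermo@dG0[[id]] + Mi)
  }

  ## Variant-group exclusivity.
  for (g in tc@variantGroups) {
    if (length(g) < 2L) next
    p <- mpAddRow(p, paste0("z_", g), rep(1, length(g)), ub = 1)
  }

  ## SubMDF constraints.
  if (useBSub) {
    p <- mpSetBounds(p, "B", lb = config@bMin)
    for (id in intersect(subset, thermoIds)) {
      s <- tc@model@stoich[[id]]
      keep <- setdiff(names(s), lc$fixed)
      Mi <- max(env$Bub - env$fMin[[id]] + 1, 1)
      vars <- c("BSub", paste0("x_", keep), paste0("z_", id))
      coefs <- c(1, rt * unname(s[keep]), Mi)
      p <- mpAddRow(p, vars, coefs, ub = -tc@thermo@dG0[[id]] + Mi)
    }
  }

  ## Demanded-optimum constraint (>= optimum - band; avoids MILP equality
  ## brittleness).
  if (!is.null(fixLevel)) {
    band <- fixLevel$band %||% MDF_EQUALITY_BAND
    tgt <- if (identical(fixLevel$kind, "BSub")) "BSub" else "B"
    p <- mpAddRow(p, tgt, 1, lb = fixLevel$value - band)
  }

  ## Swap gating r_i <= w_i * ub_i over the complementary-specificity set.
  if (!is.null(swapSet)) {
    p <- mpSetBinary(p, paste0("w_", names(swapSet)))
    for (id in names(swapSet)) {
      if (swapSet[[id]] <= 0) next
      p <- mpAddRow(p, c(paste0("r_", id), paste0("w_", id)),
                    c(1, -swapSet[[id]]), ub = 0)
    }
  }

  ## User hook D r <= d.
  for (ex in constraints$extra %||% list())
    p <- mpAddRow(p, paste0("r_", ex$rxns), ex$coefs, ub = ex$ub)

  if (!is.null(relaxable)) p <- mpSetBinary(p, paste0("u_", relaxable))

  ## Objective.
  if (identical(objective, "B")) p <- mpSetObjective(p, "B", 1)
  else if (identical(objective, "BSub")) p <- mpSetObjective(p, "BSub", 1)
  else if (identical(objective, "relaxCount")) {
    p$maximize <- FALSE
    p <- mpSetObjective(p, paste0("u_", relaxable), rep(1, length(relaxable)))
  } else {
    p$maximize <- isTRUE(objective$maximize)
    p <- mpSetObjective(p, objective$vars, objective$coefs)
  }
  p$meta <- list(bigM = bigM, rxns = rxns, mets = mets, thermoIds = thermoIds)
  p
}

## Turn a worker result into an MdfSolution.
asMdfSolution <- function(tc, prob, res, config, objectiveLabel = "MDF") {
  status <- switch(res$status, optimal = "optimal", infeasible = "infeasible",
                   unbounded = "unbounded", "error")
  if (!identical(status, "optimal"))
    return(new("MdfSolution", status = status, objective = objectiveLabel))
  x <- res$x
  r <- x[paste0("r_", prob$meta$rxns)]
  names(r) <- prob$meta$rxns
  lx <- x[paste0("x_", prob$meta$mets)]
  names(lx) <- prob$meta$mets
  z <- x[paste0("z_", prob$meta$rxns)]
  names(z) <- prob$meta$rxns
  f <- vapply(prob$meta$thermoIds, function(id) drivingForce(id, lx, tc), 0)
  B <- unname(x["B"])
  BSub <- if ("BSub" %in% names(x)) unname(x["BSub"]) else numeric(0)
  new("MdfSolution", B = B, BSub = BSub, fluxes = r, logConc = lx, z = z,
      drivingForces = f, status = "optimal",
      activeSet = prob$meta$rxns[r > config@epsActive],
      objective = objectiveLabel)
}

#' Maximal network-wide driving force (MDF)
#'
#' Solves the MILP maximizing the value `B` such that a steady-state flux
#' distribution within bounds exists in which every active thermo-constrained
#' reaction has driving force at least `B`, with metabolite concentrations
#' free within their bounds and at most one member of each variant group
#' active. `B` may be negative; its absolute value then measures the distance
#' from thermodynamic feasibility. Stoichiometric infeasibility (no flux
#' distribution satisfies the demands at all) is reported as status
#' `infeasible`, distinct from a negative-`B` optimum.
#'
#' @param tcosa a [TcosaModel-class].
#' @param constraints optional list: `growthMin` (lower bound on the objective
#'   flux), `fixedFluxes` (named numeric), `blocked` (reaction ids), `extra`
#'   (list of `list(rxns, coefs, ub)` linear flux constraints).
#' @param config a [MilpConfig-class].
#' @return an [MdfSolution-class].
#' @export
solveMdf <- function(tcosa, constraints = list(), config = milpConfig()) {
  prob <- buildDfProblem(tcosa, constraints, config, objective = "B")
  res <- solveMilp(prob, config)
  sol <- asMdfSolution(tcosa, prob, res, config, "MDF")
  auditBigM(sol, prob$meta$bigM)
  sol
}

#' Maximal driving force within a reaction subset (SubMDF)
#'
#' Maximizes `B_sub`, the driving-force floor over the subset `S` of active
#' reactions, while the network-wide MDF `B` only needs to stay above the
#' feasibility floor `bMin` (0.1 kJ/mol by default), so that the solution
#' remains thermodynamically feasible in the entire network. `B_sub` is at
#' least as high as the plain MDF of the same instance.
#'
#' @inheritParams solveMdf
#' @param subset non-empty character vector of reaction ids (the subnetwork).
#' @return an [MdfSolution-class] with both `B` and `B_sub`.
#' @export
solveSubMdf <- function(tcosa, subset, constraints = list(), config = milpConfig()) {
  if (!length(subset)) stop("subset must be non-empty")
  prob <- buildDfProblem(tcosa, constraints, config, objective = "BSub",
                         subset = subset)
  res <- solveMilp(prob, config)
  sol <- asMdfSolution(tcosa, prob, res, config, "SubMDF")
  auditBigM(sol, prob$meta$bigM)
  sol
}

## Post-solve audit: every driving force must lie strictly below big-M,
## otherwise the deactivation constant was not large enough.
auditBigM <- function(sol, bigM) {
  if (identical(sol@status, "optimal") && length(sol@drivingForces) &&
      max(sol@drivingForces) >= bigM)
    warning("big-M (", bigM, ") does not dominate the driving forces; ",
            "increase the fixed value or use auto mode")
  invisible(sol)
}

## Default SubMDF subset: all reactions derived from cofactor-duplicated
## groups (the redox-variant reactions present in the model).
redoxSubset <- function(tc) {
  prov <- tc@provenance
  ids <- union(prov$id[!is.na(prov$role)], tc@dualCofactorReactions)
  ids[tc@thermoActive[ids]]
}
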