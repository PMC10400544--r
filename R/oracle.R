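## Exhaustive reference oracle for small networks.
##
## Independent of the MILP builder: enumerates candidate active sets
## explicitly, checks each for stoichiometric achievability with a small
## feasibility LP, and maximizes the driving-force floor with a second LP over
## the concentrations only. The MILP path is validated against this oracle on
## randomized toy instances.

## effective bounds after the usual constraint list
effectiveBounds <- function(m, constraints) {
  lb <- pmax(m@lb, 0); ub <- m@ub
  if (!is.null(constraints$blocked)) {
    lb[constraints$blocked] <- 0; ub[constraints$blocked] <- 0
  }
  if (!is.null(constraints$fixedFluxes)) {
    ff <- constraints$fixedFluxes
    lb[names(ff)] <- ff; ub[names(ff)] <- ff
  }
  if (!is.null(constraints$growthMin)) {
    g <- m@objectiveReaction
    lb[g] <- max(lb[g], constraints$growthMin)
  }
  list(lb = lb, ub = ub)
}

## all admissible active-set bitmasks
admissibleMasks <- function(tc, lb) {
  q <- length(tc@model@rxnId)
  idx <- stats::setNames(seq_len(q), tc@model@rxnId)
  mandatory <- sum(bitwShiftL(1L, idx[lb > 1e-12] - 1L))
  groupMasks <- vapply(Filter(function(g) length(g) >= 2L, tc@variantGroups),
                       function(g) sum(bitwShiftL(1L, idx[g] - 1L)), 0)
  masks <- 0:(2L^q - 1L)
  keep <- bitwAnd(masks, mandatory) == mandatory
  for (gm in groupMasks) {
    pop <- vapply(bitwAnd(masks, gm), function(v) sum(bitwAnd(bitwShiftR(v, 0:30), 1L)), 0)
    keep <- keep & (pop <= 1)
  }
  masks[keep]
}

maskMembers <- function(mask, rxns) {
  rxns[bitwAnd(bitwShiftR(mask, seq_along(rxns) - 1L), 1L) == 1L]
}

## feasibility LP for one active set
subsetFeasProblem <- function(m, lb, ub, members) {
  p <- fbaProblem(m, m@objectiveReaction)
  ## fbaProblem applied the raw model bounds; overwrite with the effective
  ## ones and switch off everything outside the candidate set
  lb2 <- lb; ub2 <- ub
  off <- setdiff(m@rxnId, members)
  lb2[off] <- 0; ub2[off] <- 0
  p <- mpSetBounds(p, paste0("r_", m@rxnId), lb = unname(lb2), ub = unname(ub2))
  p$obj[] <- 0
  p
}

## concentration LP for one active set; objective = "B", "BSub" or
## list(rho = c(var = coef), maximize =, level =) for the ratio oracle
subsetThermoProblem <- function(tc, members, env, objective = "B",
                                subset = NULL, bMin = 0.1, level = NULL,
                                band = MDF_EQUALITY_BAND) {
  m <- tc@model
  lc <- env$lc
  rt <- env$rt
  thermoIds <- intersect(members, thermoConstrained(tc))
  subIds <- intersect(thermoIds, subset %||% character(0))
  vn <- c(paste0("x_", m@metId), "B")
  if (identical(objective, "BSub") || (is.list(objective) && !is.null(subset)))
    vn <- c(vn, "BSub")
  p <- milpProblem(vn, maximize = TRUE)
  p <- mpSetBounds(p, paste0("x_", m@metId), lb = unname(lc$lo[m@metId]),
                   ub = unname(lc$hi[m@metId]))
  if (length(lc$fixed)) p <- mpSetBounds(p, paste0("x_", lc$fixed), lb = 0, ub = 0)
  p <- mpSetBounds(p, "B", lb = env$Blb, ub = env$Bub)
  if ("BSub" %in% vn) p <- mpSetBounds(p, "BSub", lb = env$Blb, ub = env$Bub)

  addDf <- function(p, id, who) {
    s <- m@stoich[[id]]
    keep <- setdiff(names(s), lc$fixed)
    mpAddRow(p, c(who, paste0("x_", keep)), c(1, rt * unname(s[keep])),
             ub = -tc@thermo@dG0[[id]])
  }
  for (id in thermoIds) p <- addDf(p, id, "B")
  if (identical(objective, "B")) {
    p <- mpSetObjective(p, "B", 1)
  } else if (identical(objective, "BSub")) {
    p <- mpSetBounds(p, "B", lb = bMin)
    for (id in subIds) p <- addDf(p, id, "BSub")
    p <- mpSetObjective(p, "BSub", 1)
  } else {
    ## ratio mode at a demanded driving-force level
    if (is.null(subset)) {
      p <- mpSetBounds(p, "B", lb = level - band)
    } else {
      p <- mpSetBounds(p, "B", lb = bMin)
      for (id in subIds) p <- addDf(p, id, "BSub")
      p <- mpSetBounds(p, "BSub", lb = level - band)
    }
    p$maximize <- isTRUE(objective$maximize)
    p <- mpSetObjective(p, names(objective$rho), unname(objective$rho))
  }
  p
}

oracleGuard <- function(tc, maxReactions, maxMetabolites) {
  if (length(tc@model@rxnId) > maxReactions ||
      length(tc@model@metId) > maxMetabolites)
    stop("model too large for the exhaustive oracle (",
         length(tc@model@rxnId), " reactions, ", length(tc@model@metId),
         " metabolites)")
}

#' Reference MDF/SubMDF by exhaustive active-set enumeration
#'
#' Enumerates every admissible active set (respecting variant-group
#' exclusivity and demanded fluxes), keeps those achievable by a steady-state
#' flux distribution, and maximizes the driving-force floor over the
#' concentration polytope of each; the maximum over sets is the reference
#' value. Intended as an independent test oracle for [solveMdf()] /
#' [solveSubMdf()] on networks of up to about a dozen reactions.
#'
#' @inheritParams solveMdf
#' @param objective `"MDF"` or `"SubMDF"`.
#' @param subset subnetwork reaction ids (SubMDF mode).
#' @param maxReactions,maxMetabolites size guard.
#' @return the reference value in kJ/mol (`NA` when no admissible active set
#'   is stoichiometrically feasible), with the best active set in attribute
#'   `support`.
#' @export
bruteForceMdf <- function(tcosa, constraints = list(), config = milpConfig(),
                          objective = c("MDF", "SubMDF"), subset = NULL,
                          maxReactions = 12L, maxMetabolites = 14L) {
  objective <- match.arg(objective)
  oracleGuard(tcosa, maxReactions, maxMetabolites)
  m <- tcosa@model
  eb <- effectiveBounds(m, constraints)
  masks <- admissibleMasks(tcosa, eb$lb)
  memb <- lapply(masks, maskMembers, rxns = m@rxnId)
  feas <- solveMilpBatch(lapply(memb, function(mem)
    subsetFeasProblem(m, eb$lb, eb$ub, mem)), config)
  ok <- vapply(feas, function(r) identical(r$status, "optimal"), NA)
  if (!any(ok)) return(NA_real_)
  memb <- memb[ok]
  env <- dfEnvelope(tcosa, config)
  obj <- if (objective == "MDF") "B" else "BSub"
  if (objective == "SubMDF" && is.null(subset)) subset <- redoxSubset(tcosa)
  thermo <- solveMilpBatch(lapply(memb, function(mem)
    subsetThermoProblem(tcosa, mem, env, obj, subset, config@bMin)), config)
  vals <- vapply(thermo, function(r)
    if (identical(r$status, "optimal")) r$objective else -Inf, 0)
  if (all(vals == -Inf)) return(NA_real_)
  best <- which.max(vals)
  structure(vals[best], support = memb[[best]])
}

#' Reference ratio-variability range by exhaustive enumeration
#'
#' Companion oracle to [ratioRange()]: enumerates feasible active sets whose
#' driving-force optimum reaches the previously computed (Sub)MDF value and
#' extremizes the logarithmized cofactor-ratio quotient over each set's
#' concentration polytope.
#'
#' @inheritParams bruteForceMdf
#' @param level the fixed (Sub)MDF optimum.
#' @param band demanded-optimum tolerance (kJ/mol).
#' @return c(rhoMin, rhoMax).
#' @export
bruteForceRatioRange <- function(tcosa, level, constraints = list(),
                                 config = milpConfig(),
                                 objective = c("MDF", "SubMDF"), subset = NULL,
                                 band = MDF_EQUALITY_BAND,
                                 maxReactions = 12L, maxMetabolites = 14L) {
  objective <- match.arg(objective)
  oracleGuard(tcosa, maxReactions, maxMetabolites)
  m <- tcosa@model
  eb <- effectiveBounds(m, constraints)
  masks <- admissibleMasks(tcosa, eb$lb)
  memb <- lapply(masks, maskMembers, rxns = m@rxnId)
  feas <- solveMilpBatch(lapply(memb, function(mem)
    subsetFeasProblem(m, eb$lb, eb$ub, mem)), config)
  memb <- memb[vapply(feas, function(r) identical(r$status, "optimal"), NA)]
  if (!length(memb)) stop("no stoichiometrically feasible active set")
  env <- dfEnvelope(tcosa, config)
  if (objective == "SubMDF" && is.null(subset)) subset <- redoxSubset(tcosa)
  useSubset <- if (objective == "SubMDF") subset else NULL

  pools <- tcosa@cofactors@pools
  p1 <- pools[[if ("NAD" %in% names(pools)) "NAD" else 1L]]
  p2 <- pools[[if ("NADP" %in% names(pools)) "NADP" else 2L]]
  rho <- stats::setNames(c(1, -1, -1, 1),
                         paste0("x_", c(p1[["red"]], p1[["ox"]],
                                        p2[["red"]], p2[["ox"]])))
  probs <- list(); tags <- list()
  for (k in seq_along(memb)) for (mx in c(TRUE, FALSE)) {
    probs[[length(probs) + 1L]] <- subsetThermoProblem(
      tcosa, memb[[k]], env, objective = list(rho = rho, maximize = mx),
      subset = useSubset, bMin = config@bMin, level = level, band = band)
    tags[[length(tags) + 1L]] <- mx
  }
  res <- solveMilpBatch(probs, config)
  hi <- -Inf; lo <- Inf
  for (k in seq_along(res)) {
    if (!identical(res[[k]]$status, "optimal")) next
    if (isTRUE(tags[[k]])) hi <- max(hi, res[[k]]$objective)
    else lo <- min(lo, res[[k]]$objective)
  }
  if (!is.finite(hi) || !is.finite(lo))
    stop("demanded driving-force level is unreachable by any active set")
  c(rhoMin = lo, rhoMax = hi)
}
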